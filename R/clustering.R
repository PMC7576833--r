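#' Pairwise RMSD matrix over trajectory frames
#'
#' Entry (i, j) is the RMSD over `rmsd_region` after superposing frame i on
#' frame j using `fit_region` (Calpha atoms by default), i.e. the same
#' quantity as [region_rmsd()] between frames of one trajectory.
#'
#' @param traj a [new_trajectory()].
#' @param rmsd_region residue ids whose displacement is measured.
#' @param fit_region residue ids used for the superposition fit (default:
#'   `rmsd_region`, i.e. plain best-fit RMSD).
#' @param elety atom-name filter, default `"CA"`.
#' @param frames frame subset (default all).
#' @return symmetric matrix (Angstrom) with zero diagonal.
#' @export
pairwise_rmsd_matrix <- function(traj, rmsd_region, fit_region = NULL,
                                 elety = "CA", frames = NULL) {
  frames <- frames %||% seq_len(n_frames(traj))
  if (length(frames) < 2L) stopf("need at least 2 frames")
  fit_region <- fit_region %||% rmsd_region
  ifit <- select_atoms(traj$topology, residues = fit_region, elety = elety)
  irms <- select_atoms(traj$topology, residues = rmsd_region, elety = elety)
  if (length(irms) == 0L) stopf("empty rmsd selection")
  if (length(ifit) < 3L) stopf("fit selection needs at least 3 atoms")
  n <- length(frames)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    A <- frame_coords(traj, frames[i])
    for (j in (i + 1L):n) {
      B <- frame_coords(traj, frames[j])
      P <- A[ifit, , drop = FALSE]; Q <- B[ifit, , drop = FALSE]
      cp <- colMeans(P); cq <- colMeans(Q)
      H <- crossprod(sweep(P, 2, cp), sweep(Q, 2, cq))
      s <- svd(H)
      R <- s$u %*% diag(c(1, 1, sign(det(s$u %*% t(s$v))))) %*% t(s$v)
      Ar <- sweep(sweep(A[irms, , drop = FALSE], 2, cp) %*% R, 2, cq, `+`)
      D[i, j] <- D[j, i] <- sqrt(mean(rowSums((Ar - B[irms, , drop = FALSE])^2)))
    }
  }
  D
}

#' Average-linkage clustering with a distance cutoff
#'
#' Agglomerative clustering under the average-linkage criterion: clusters
#' are merged while the smallest average inter-cluster distance does not
#' exceed the cutoff (the cpptraj-style epsilon criterion; the value used for
#' seeding antibody loop ensembles is 1.2 Angstrom). The representative of
#' each cluster is its medoid (minimum mean distance to members).
#'
#' @param dist_matrix symmetric non-negative distance matrix.
#' @param cutoff distance cutoff epsilon (same units as the matrix).
#' @return `"cluster_result"`: list with `labels` (1..K, dense),
#'   `representatives` (frame index per cluster), `k`, `cutoff`,
#'   `method = "average"`.
#' @export
average_linkage_cluster <- function(dist_matrix, cutoff) {
  D <- as.matrix(dist_matrix)
  if (nrow(D) != ncol(D) || max(abs(D - t(D))) > 1e-8)
    stopf("distance matrix must be symmetric")
  if (any(D < 0)) stopf("distance matrix must be non-negative")
  n <- nrow(D)
  if (n == 1L) {
    labels <- 1L
  } else {
    hc <- stats::hclust(stats::as.dist(D), method = "average")
    labels <- stats::cutree(hc, h = cutoff)
  }
  ## dense relabel in order of first appearance
  labels <- as.integer(factor(labels, levels = unique(labels)))
  k <- max(labels)
  reps <- integer(k)
  for (c in seq_len(k)) {
    mem <- which(labels == c)
    if (length(mem) == 1L) reps[c] <- mem
    else reps[c] <- mem[which.min(rowMeans(D[mem, mem, drop = FALSE]))]
  }
  structure(list(labels = labels, representatives = reps, k = k,
                 cutoff = cutoff, method = "average"),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("cluster result: %d clusters over %d frames (cutoff %.3g)\n",
              x$k, length(x$labels), x$cutoff))
  print(table(x$labels))
  invisible(x)
}

#' Geometric clustering of a single CDR loop
#'
#' Clusters trajectory frames by the conformation of one loop: frames are
#' superposed on the framework (all Fv residues outside the CDR loops, or a
#' user-supplied fit region) and the loop-atom RMSD matrix is clustered by
#' average linkage at the given cutoff.
#'
#' @param traj a [new_trajectory()].
#' @param regions [annotate_regions()] object.
#' @param loop region name, e.g. `"CDR_L1"`.
#' @param cutoff linkage cutoff in Angstrom (default 1.2).
#' @param fit_region framework residues for the fit; default the VL+VH
#'   residues not in any CDR set.
#' @param elety atom filter, default `"CA"`.
#' @param frames frame subset.
#' @return A `"cluster_result"` (see [average_linkage_cluster()]).
#' @export
per_loop_cluster <- function(traj, regions, loop, cutoff = 1.2,
                             fit_region = NULL, elety = "CA", frames = NULL) {
  if (!loop %in% names(regions)) stopf("loop '%s' not in regions", loop)
  if (is.null(fit_region)) {
    cdr_all <- unlist(regions[intersect(names(regions),
                                        names(.domain_of_cdr))],
                      use.names = FALSE)
    fit_region <- setdiff(unique(c(regions$VL, regions$VH)), cdr_all)
  }
  D <- pairwise_rmsd_matrix(traj, rmsd_region = regions[[loop]],
                            fit_region = fit_region, elety = elety,
                            frames = frames)
  out <- average_linkage_cluster(D, cutoff)
  out$loop <- loop
  out$fit_region <- fit_region
  out
}

#' Assign frames to canonical-cluster medians by circular torsion distance
#'
#' Each frame's loop torsion vector is compared to user-supplied reference
#' median torsion vectors (e.g. PyIgClassify-style canonical cluster medians
#' such as "L1-11-3") under the mean circular distance
#' `d = mean(min(|dtheta|, 360 - |dtheta|))`. The nearest reference wins;
#' ties go to the lexicographically smaller label; frames farther than
#' `threshold` from every reference are labelled `"unassigned"`.
#'
#' @param ts a [new_torsion_series()] (frames x torsions, degrees).
#' @param references named list of numeric median torsion vectors, each the
#'   same length as `ncol(ts)`.
#' @param threshold mean circular distance cutoff in degrees (default 40).
#' @return `"canonical_assignment"`: data.frame with `label` and `distance`
#'   per frame.
#' @export
assign_canonical <- function(ts, references, threshold = 40) {
  m <- unclass(ts)
  bad <- vapply(references, function(r) length(r) != ncol(m), logical(1))
  if (any(bad))
    stopf("reference '%s' has %d torsions but series has %d",
          names(references)[bad][1L],
          length(references[[which(bad)[1L]]]), ncol(m))
  labs <- sort(names(references))   # lexicographic tie order
  D <- vapply(labs, function(l) {
    ref <- references[[l]]
    rowMeans(circ_diff(m, matrix(ref, nrow(m), ncol(m), byrow = TRUE)))
  }, numeric(nrow(m)))
  D <- matrix(D, nrow = nrow(m))
  best <- max.col(-D, ties.method = "first")
  dist <- D[cbind(seq_len(nrow(m)), best)]
  label <- labs[best]
  label[dist > threshold] <- "unassigned"
  structure(data.frame(label = label, distance = dist,
                       stringsAsFactors = FALSE),
            class = c("canonical_assignment", "data.frame"),
            threshold = threshold)
}

#' Export a cluster result: label table and representative structures
#'
#' Writes the per-frame label table to CSV and, when a trajectory is given,
#' the representative frames as a multi-model PDB.
#'
#' @param cl a `"cluster_result"`.
#' @param file CSV path for the label table.
#' @param traj optional trajectory to extract representatives from.
#' @param pdb_file multi-model PDB path for the representatives.
#' @return invisible list of written paths.
#' @export
export_cluster_result <- function(cl, file, traj = NULL, pdb_file = NULL) {
  utils::write.csv(data.frame(frame = seq_along(cl$labels),
                              cluster = cl$labels), file, row.names = FALSE)
  paths <- list(labels = file)
  if (!is.null(traj) && !is.null(pdb_file)) {
    write_trajectory_pdb(traj, pdb_file, frames = cl$representatives)
    paths$representatives <- pdb_file
  }
  invisible(paths)
}
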