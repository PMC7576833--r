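#' Backbone torsion time series for a residue set
#'
#' Computes phi and psi backbone dihedrals per frame for the requested
#' residues: phi(i) from C(i-1), N(i), CA(i), C(i); psi(i) from N(i), CA(i),
#' C(i), N(i+1); IUPAC sign convention. Angles whose neighbouring residue is
#' absent (chain termini, or a neighbour outside the topology) are omitted
#' rather than padded with NA.
#'
#' @param traj a [new_trajectory()].
#' @param residues residue-id character vector (see [annotate_regions()]).
#' @param angles which torsions to compute, subset of `c("phi", "psi")`.
#' @param on_degenerate `"error"` (default) raises on collinear backbone
#'   atoms; `"drop"` emits NaN for the degenerate frame and drops columns
#'   that contain any NaN, with a message.
#' @return Object of class `"torsion_series"`: `frames x angles` numeric
#'   matrix in degrees, range (-180, 180], with a `labels` attribute
#'   (data.frame: `res_id`, `angle`).
#' @export
backbone_torsions <- function(traj, residues, angles = c("phi", "psi"),
                              on_degenerate = c("error", "drop")) {
  on_degenerate <- match.arg(on_degenerate)
  angles <- match.arg(angles, c("phi", "psi"), several.ok = TRUE)
  top <- traj$topology
  at <- top$atoms
  res_order <- top$residues
  bb_index <- function(res, name) {
    i <- which(at$res_id == res & trimws(at$elety) == name)
    if (length(i) == 0L) return(NA_integer_)
    i[1L]
  }
  chain_of <- function(res) at$chain[match(res, at$res_id)]
  nfr <- n_frames(traj)
  cols <- list()
  labs <- list()
  for (res in residues) {
    pos <- match(res, res_order)
    if (is.na(pos)) stopf("residue '%s' absent from topology", res)
    iN <- bb_index(res, "N"); iCA <- bb_index(res, "CA"); iC <- bb_index(res, "C")
    if (is.na(iN) || is.na(iCA) || is.na(iC)) {
      missing_atom <- c("N", "CA", "C")[which(is.na(c(iN, iCA, iC)))[1L]]
      stopf("residue '%s' lacks backbone atom %s", res, missing_atom)
    }
    prev <- if (pos > 1L) res_order[pos - 1L] else NA
    nxt <- if (pos < length(res_order)) res_order[pos + 1L] else NA
    if (!is.na(prev) && chain_of(prev) != chain_of(res)) prev <- NA
    if (!is.na(nxt) && chain_of(nxt) != chain_of(res)) nxt <- NA
    if ("phi" %in% angles && !is.na(prev)) {
      iCp <- bb_index(prev, "C")
      if (!is.na(iCp)) {
        cols[[length(cols) + 1L]] <- .torsion_column(traj, c(iCp, iN, iCA, iC),
                                                     on_degenerate, res, "phi")
        labs[[length(labs) + 1L]] <- c(res, "phi")
      }
    }
    if ("psi" %in% angles && !is.na(nxt)) {
      iNn <- bb_index(nxt, "N")
      if (!is.na(iNn)) {
        cols[[length(cols) + 1L]] <- .torsion_column(traj, c(iN, iCA, iC, iNn),
                                                     on_degenerate, res, "psi")
        labs[[length(labs) + 1L]] <- c(res, "psi")
      }
    }
  }
  if (length(cols) == 0L) stopf("no computable torsions for the given residues")
  m <- do.call(cbind, cols)
  lab <- do.call(rbind, labs)
  lab <- data.frame(res_id = lab[, 1L], angle = lab[, 2L],
                    stringsAsFactors = FALSE)
  ## drop NaN columns (permissive mode)
  bad <- apply(m, 2L, function(x) any(is.nan(x)))
  if (any(bad)) {
    message(sprintf("dropping %d degenerate torsion column(s): %s", sum(bad),
                    paste(paste0(lab$res_id[bad], ":", lab$angle[bad]),
                          collapse = ", ")))
    m <- m[, !bad, drop = FALSE]
    lab <- lab[!bad, , drop = FALSE]
  }
  new_torsion_series(m, lab)
}

.torsion_column <- function(traj, idx, on_degenerate, res, angle_name) {
  p <- lapply(1:4, function(k) {
    x <- traj$coords[, idx[k], , drop = FALSE]
    dim(x) <- c(dim(traj$coords)[1L], 3L)
    x
  })
  if (on_degenerate == "error") {
    dihedral_angle(p[[1L]], p[[2L]], p[[3L]], p[[4L]])
  } else {
    tryCatch(dihedral_angle(p[[1L]], p[[2L]], p[[3L]], p[[4L]]),
             error = function(e) rep(NaN, dim(traj$coords)[1L]))
  }
}

#' Construct a torsion series
#'
#' @param values `frames x angles` matrix in degrees (-180, 180].
#' @param labels data.frame with columns `res_id` and `angle`.
#' @return `"torsion_series"` object.
#' @export
new_torsion_series <- function(values, labels) {
  values <- as.matrix(values)
  if (nrow(labels) != ncol(values))
    stopf("labels (%d) do not match torsion columns (%d)",
          nrow(labels), ncol(values))
  values[] <- wrap_angle(values)
  colnames(values) <- paste0(labels$res_id, ":", labels$angle)
  structure(values, class = c("torsion_series", "matrix", "array"),
            labels = labels)
}

#' Sin/cos feature matrix from torsions
#'
#' Maps every retained torsion to the pair (sin, cos), the standard
#' periodicity-free feature space for torsion dynamics and the basis of the
#' CDR-loop collective variable. Column order follows the torsion label
#' order, (sin, cos) per torsion.
#'
#' @param ts a [new_torsion_series()] (or plain matrix in degrees).
#' @param subset optional column indices or label names to retain
#'   (e.g. only psi torsions).
#' @return `"feature_matrix"`: `frames x (2 * torsions)` matrix with a
#'   `labels` data.frame attribute (`res_id`, `angle`, `fun`).
#' @export
sincos_features <- function(ts, subset = NULL) {
  m <- unclass(ts)
  lab <- attr(ts, "labels")
  if (is.null(lab))
    lab <- data.frame(res_id = colnames(m) %||% paste0("t", seq_len(ncol(m))),
                      angle = "torsion", stringsAsFactors = FALSE)
  if (!is.null(subset)) {
    if (is.character(subset)) subset <- match(subset, colnames(m))
    m <- m[, subset, drop = FALSE]
    lab <- lab[subset, , drop = FALSE]
  }
  if (ncol(m) == 0L) stopf("empty torsion subset")
  r <- deg2rad(m)
  out <- matrix(NA_real_, nrow(m), 2L * ncol(m))
  out[, seq(1L, by = 2L, length.out = ncol(m))] <- sin(r)
  out[, seq(2L, by = 2L, length.out = ncol(m))] <- cos(r)
  labs <- data.frame(res_id = rep(lab$res_id, each = 2L),
                     angle = rep(lab$angle, each = 2L),
                     fun = rep(c("sin", "cos"), ncol(m)),
                     stringsAsFactors = FALSE)
  colnames(out) <- paste0(labs$res_id, ":", labs$angle, ":", labs$fun)
  structure(out, class = c("feature_matrix", "matrix", "array"), labels = labs)
}

#' Torsion-space collective variable (weighted sin/cos combination)
#'
#' The scalar collective variable used to drive enhanced sampling of CDR
#' loops: a linear combination of sines and cosines of loop psi torsions.
#' Weights are user-supplied (one per sin/cos feature column).
#'
#' @param ts torsion series (typically psi-only, see [sincos_features()]).
#' @param weights numeric, length `2 * n_torsions`.
#' @param subset optional torsion subset forwarded to [sincos_features()].
#' @return per-frame numeric vector.
#' @export
metadynamics_cv <- function(ts, weights, subset = NULL) {
  f <- sincos_features(ts, subset = subset)
  if (length(weights) != ncol(f))
    stopf("weights length (%d) must equal feature count (%d)",
          length(weights), ncol(f))
  drop(unclass(f) %*% weights)
}

#' Write a feature matrix (or torsion series) to CSV
#'
#' @param x matrix with column names.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_feature_csv <- function(x, file) {
  utils::write.csv(as.data.frame(unclass(x)), file, row.names = FALSE)
  invisible(file)
}
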