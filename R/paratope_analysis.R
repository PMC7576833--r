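## Synthesis stage: per-macrostate ensembles, per-state angle
## distributions, macrostate projection onto per-loop surfaces, and
## CDR loop co-occurrence.

#' Partition frames into macrostate ensembles
#'
#' Maps every frame through its microstate's crisp PCCA+ macrostate.
#' Frames whose microstate fell outside the MSM's connected set go to an
#' `"unassigned"` pool. The representative frame of a macrostate is the
#' frame closest (in the clustering space) to the center of the
#' macrostate's highest-probability microstate.
#'
#' @param micro a [kmeans_microstates()] model (its `dtrajs` cover the
#'   frames in order).
#' @param msm an [estimate_msm()] model built from those dtrajs.
#' @param macro a [pcca_plus()] object.
#' @param coords optional projected coordinates (matrix or segment list)
#'   used to pick representative frames.
#' @return `"macrostate_ensembles"`: list of per-macrostate lists with
#'   `frames` (global frame indices), `probability`, `representative`
#'   (frame index or NA); plus attribute `unassigned` (frame indices).
#' @export
macrostate_ensembles <- function(micro, msm, macro, coords = NULL) {
  dtraj <- unlist(micro$dtrajs)
  state_of <- rep(NA_integer_, micro$k)
  state_of[msm$active] <- macro$crisp
  lab <- state_of[dtraj]
  if (!is.null(coords)) {
    X <- do.call(rbind, as_segment_list(coords))
    if (nrow(X) != length(dtraj))
      stopf("coords frames (%d) do not match dtraj frames (%d)",
            nrow(X), length(dtraj))
  }
  out <- vector("list", macro$m)
  for (a in seq_len(macro$m)) {
    frames <- which(lab == a)
    rep_frame <- NA_integer_
    micro_in_a <- msm$active[macro$crisp == a]
    if (length(micro_in_a)) {
      top_micro <- micro_in_a[which.max(msm$pi[match(micro_in_a, msm$active)])]
      cand <- which(dtraj == top_micro)
      if (length(cand)) {
        if (!is.null(coords)) {
          ctr <- micro$centers[top_micro, ]
          d2 <- rowSums(sweep(X[cand, , drop = FALSE], 2L, ctr)^2)
          rep_frame <- cand[which.min(d2)]
        } else rep_frame <- cand[1L]
      }
    }
    out[[a]] <- list(id = a, frames = frames,
                     probability = macro$probabilities[a],
                     representative = rep_frame)
  }
  structure(out, class = "macrostate_ensembles",
            unassigned = which(is.na(lab)))
}

#' @export
print.macrostate_ensembles <- function(x, ...) {
  cat(sprintf("%d macrostate ensembles (%d unassigned frames)\n",
              length(x), length(attr(x, "unassigned"))))
  for (e in x)
    cat(sprintf("  state %d: %6d frames, p = %.3f, representative frame %s\n",
                e$id, length(e$frames), e$probability, e$representative))
  invisible(x)
}

#' Per-macrostate angle distributions
#'
#' Histograms an angle series (interface or elbow angle) separately for
#' each macrostate ensemble on a shared binning, and summarizes each state
#' by median and IQR. The shift between two states is the difference of
#' medians, with a bootstrap confidence interval. A crystal-structure
#' reference angle can be attached for plotting as a reference line.
#'
#' @param ensembles a [macrostate_ensembles()] object.
#' @param angles numeric per-frame angle series, frame-aligned with the
#'   ensembles.
#' @param breaks number of shared histogram bins (default 72).
#' @param reference optional reference angle (degrees).
#' @param boot bootstrap resamples for shift intervals (default 200).
#' @param seed seed for the bootstrap.
#' @return `"state_angle_dist"`: list with `histograms` (per state, counts
#'   on shared `breaks`), `summary` data.frame (state, n, median, iqr),
#'   `shifts` data.frame (pairwise median differences with bootstrap CI),
#'   `breaks`, `reference`.
#' @export
per_state_angle_distribution <- function(ensembles, angles, breaks = 72L,
                                         reference = NULL, boot = 200L,
                                         seed = 1L) {
  nfr <- max(c(unlist(lapply(ensembles, `[[`, "frames")), 0L),
             length(attr(ensembles, "unassigned")))
  if (length(angles) < nfr)
    stopf("angle series (%d frames) shorter than ensemble frames (max index %d)",
          length(angles), nfr)
  brk <- seq(-180, 180, length.out = breaks + 1L)
  hists <- list()
  summ <- list()
  for (e in ensembles) {
    if (length(e$frames) == 0L) {
      hists[[as.character(e$id)]] <- NULL
      warning(sprintf("macrostate %d has no frames; no histogram", e$id))
      next
    }
    a <- wrap_angle(as.numeric(angles[e$frames]))
    hists[[as.character(e$id)]] <- hist(a, breaks = brk, plot = FALSE)$counts
    summ[[length(summ) + 1L]] <- data.frame(
      state = e$id, n = length(a), median = stats::median(a),
      iqr = stats::IQR(a), probability = e$probability)
  }
  summary_df <- do.call(rbind, summ)
  ## pairwise median shifts with bootstrap intervals
  shifts <- list()
  set.seed(seed)
  states <- summary_df$state
  for (i in seq_along(states)) for (j in seq_along(states)) {
    if (j <= i) next
    ai <- as.numeric(angles[ensembles[[states[i]]]$frames])
    aj <- as.numeric(angles[ensembles[[states[j]]]$frames])
    d0 <- stats::median(aj) - stats::median(ai)
    bs <- replicate(boot, stats::median(sample(aj, replace = TRUE)) -
                          stats::median(sample(ai, replace = TRUE)))
    q <- stats::quantile(bs, c(0.025, 0.975), names = FALSE)
    shifts[[length(shifts) + 1L]] <- data.frame(
      from = states[i], to = states[j], shift = d0,
      ci_lo = q[1L], ci_hi = q[2L])
  }
  structure(list(histograms = hists, summary = summary_df,
                 shifts = if (length(shifts)) do.call(rbind, shifts) else NULL,
                 breaks = brk, reference = reference),
            class = "state_angle_dist")
}

#' Project macrostate representatives onto a per-loop surface
#'
#' Projects the feature rows of macrostate representative frames into a
#' loop-specific tICA space, so the global paratope states can be located
#' on an individual loop's free-energy surface.
#'
#' @param loop_model a [fit_tica()] model fitted on that loop's features.
#' @param loop_features the loop feature matrix (all frames, frame-aligned
#'   with the ensembles).
#' @param ensembles a [macrostate_ensembles()] object.
#' @param n_components components to keep (default 2).
#' @return data.frame with `state`, `frame`, and tIC coordinates.
#' @export
project_macrostates_on_loop_fes <- function(loop_model, loop_features,
                                            ensembles, n_components = 2L) {
  reps <- vapply(ensembles, function(e) e$representative, numeric(1))
  states <- vapply(ensembles, function(e) e$id, numeric(1))
  keep <- !is.na(reps)
  X <- as.matrix(unclass(loop_features))[reps[keep], , drop = FALSE]
  Y <- project_tica(loop_model, X, n_components = n_components)
  out <- data.frame(state = states[keep], frame = reps[keep])
  for (k in seq_len(ncol(Y))) out[[paste0("tIC", k)]] <- Y[, k]
  out
}

#' Cramer's V association between two label vectors
#'
#' `V = sqrt(chi2 / (n (min(r, c) - 1)))` from the Pearson chi-squared
#' statistic of the joint contingency table (empty rows/columns dropped).
#'
#' @param a,b equal-length label vectors.
#' @return scalar in `[0, 1]`.
#' @export
cramers_v <- function(a, b) {
  tab <- table(a, b)
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2L || ncol(tab) < 2L) return(0)
  chi2 <- suppressWarnings(stats::chisq.test(tab, correct = FALSE)$statistic)
  n <- sum(tab)
  as.numeric(sqrt(chi2 / (n * (min(dim(tab)) - 1L))))
}

#' CDR loop co-occurrence matrices
#'
#' For every pair of loops, counts the joint occurrence of their cluster
#' labels over frames, giving the matrix of simultaneous loop-conformation
#' populations, and summarizes each pair's association by Cramer's V.
#' All cluster results must cover the identical frame set.
#'
#' @param cluster_results named list of [average_linkage_cluster()] /
#'   [per_loop_cluster()] results (one per loop).
#' @return `"cooccurrence"`: list with `pairs` (data.frame: loop_a, loop_b,
#'   cramers_v) and `tables` (named list of joint count matrices,
#'   `"A|B"`).
#' @export
loop_cooccurrence <- function(cluster_results) {
  loops <- names(cluster_results)
  if (is.null(loops) || length(loops) < 2L)
    stopf("need at least two named cluster results")
  nfr <- vapply(cluster_results, function(cl) length(cl$labels), integer(1))
  if (length(unique(nfr)) != 1L)
    stopf("cluster results cover different frame sets: %s",
          paste(paste0(loops, "=", nfr), collapse = ", "))
  tables <- list()
  rows <- list()
  for (i in seq_along(loops)) for (j in seq_along(loops)) {
    if (j <= i) next
    la <- cluster_results[[i]]$labels
    lb <- cluster_results[[j]]$labels
    tab <- table(factor(la, levels = seq_len(max(la))),
                 factor(lb, levels = seq_len(max(lb))))
    key <- paste0(loops[i], "|", loops[j])
    tables[[key]] <- unclass(tab)
    rows[[length(rows) + 1L]] <- data.frame(
      loop_a = loops[i], loop_b = loops[j],
      cramers_v = cramers_v(la, lb), stringsAsFactors = FALSE)
  }
  structure(list(pairs = do.call(rbind, rows), tables = tables),
            class = "cooccurrence")
}

#' @export
print.cooccurrence <- function(x, ...) {
  cat("loop co-occurrence (Cramer's V):\n")
  print(x$pairs, row.names = FALSE)
  invisible(x)
}

#' Write a co-occurrence report bundle
#'
#' Exports every pairwise joint count matrix and the association summary
#' to CSV files under a directory.
#'
#' @param cooc a [loop_cooccurrence()] result.
#' @param dir output directory (created if needed).
#' @return invisible vector of written paths.
#' @export
export_cooccurrence <- function(cooc, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  f <- file.path(dir, "cooccurrence_summary.csv")
  utils::write.csv(cooc$pairs, f, row.names = FALSE)
  paths <- c(paths, f)
  for (key in names(cooc$tables)) {
    f <- file.path(dir, paste0("cooccurrence_",
                               gsub("[^A-Za-z0-9]+", "_", key), ".csv"))
    utils::write.csv(cooc$tables[[key]], f)
    paths <- c(paths, f)
  }
  invisible(paths)
}
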