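## tICA, microstating, Markov-state model estimation and validation,
## PCCA+ coarse-graining and free-energy surfaces.

as_segment_list <- function(x) {
  if (is.list(x) && !is.data.frame(x)) lapply(x, function(m) as.matrix(unclass(m)))
  else list(as.matrix(unclass(x)))
}

#' Time-lagged independent component analysis
#'
#' Estimates the slow linear collective coordinates of a feature time
#' series: solves the generalized eigenproblem `C_tau v = lambda C_0 v`
#' with the time-lagged covariance symmetrized as `(C_tau + C_tau^T)/2`
#' and a small ridge added to `C_0` for numerical rank safety. Covariances
#' are accumulated per trajectory segment; no lagged pairs cross segment
#' boundaries. Eigenvectors are `C_0`-orthonormal, eigenvalues sorted
#' descending; the implied timescale of component i is
#' `-lag / log(lambda_i)`.
#'
#' @param features a feature matrix or list of per-segment matrices
#'   (see [sincos_features()]).
#' @param lag lag time in frames.
#' @param ridge ridge added to the diagonal of `C_0` (default 1e-6).
#' @param frame_spacing optional ns per frame, stored for unit conversion.
#' @return `"tica_model"`: list with `mean`, `C0`, `Ct`, `eigenvalues`,
#'   `eigenvectors` (columns), `lag`, `ridge`, `frame_spacing`.
#' @export
fit_tica <- function(features, lag, ridge = 1e-6, frame_spacing = NULL) {
  segs <- as_segment_list(features)
  if (length(segs) == 0L) stopf("no feature segments")
  lens <- vapply(segs, nrow, integer(1))
  short <- which(lens <= lag)
  if (length(short))
    stopf("segment %d has %d frames, shorter than lag %d",
          short[1L], lens[short[1L]], lag)
  d <- ncol(segs[[1L]])
  ntot <- sum(lens)
  mu <- Reduce(`+`, lapply(segs, colSums)) / ntot
  C0 <- matrix(0, d, d); Ct <- matrix(0, d, d); npairs <- 0
  for (X in segs) {
    Xc <- sweep(X, 2L, mu)
    n <- nrow(Xc)
    A <- Xc[seq_len(n - lag), , drop = FALSE]
    B <- Xc[(lag + 1L):n, , drop = FALSE]
    C0 <- C0 + crossprod(A) + crossprod(B)
    Ct <- Ct + crossprod(A, B)
    npairs <- npairs + (n - lag)
  }
  C0 <- C0 / (2 * npairs)
  Ct <- Ct / npairs
  Ct <- (Ct + t(Ct)) / 2
  C0r <- C0 + diag(ridge, d)
  U <- tryCatch(chol(C0r), error = function(e)
    stopf("C0 is rank deficient beyond the ridge: %s", conditionMessage(e)))
  ## whitened operator: U^-T Ct U^-1, symmetric
  A1 <- forwardsolve(t(U), Ct)
  S <- t(forwardsolve(t(U), t(A1)))
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  V <- backsolve(U, e$vectors)
  structure(list(mean = mu, C0 = C0, Ct = Ct,
                 eigenvalues = e$values, eigenvectors = V,
                 lag = lag, ridge = ridge, frame_spacing = frame_spacing),
            class = "tica_model")
}

#' @export
print.tica_model <- function(x, ...) {
  cat(sprintf("tICA model: %d features, lag %d frames\n",
              length(x$mean), x$lag))
  cat("leading eigenvalues:",
      paste(sprintf("%.4f", utils::head(x$eigenvalues, 5L)), collapse = " "),
      "\n")
  invisible(x)
}

#' Project features onto tICA components
#'
#' Mean-free projection onto the leading `C_0`-orthonormal eigenvectors, so
#' each projected coordinate has unit instantaneous variance (up to sampling
#' noise).
#'
#' @param model a [fit_tica()] model.
#' @param features matrix or list of matrices with matching feature count.
#' @param n_components number of components (default: all).
#' @return matrix (or list of matrices) `frames x n_components`.
#' @export
project_tica <- function(model, features, n_components = NULL) {
  m <- n_components %||% ncol(model$eigenvectors)
  proj1 <- function(X) {
    X <- as.matrix(unclass(X))
    if (ncol(X) != length(model$mean))
      stopf("feature dimensionality (%d) does not match model (%d)",
            ncol(X), length(model$mean))
    sweep(X, 2L, model$mean) %*% model$eigenvectors[, seq_len(m), drop = FALSE]
  }
  if (is.list(features) && !is.data.frame(features)) lapply(features, proj1)
  else proj1(features)
}

#' Number of tICA components covering a kinetic-variance fraction
#'
#' Kinetic variance of component i is `lambda_i^2`; returns the smallest m
#' whose cumulative share of the total (over positive eigenvalues) reaches
#' `fraction`.
#'
#' @param model a `"tica_model"`.
#' @param fraction target fraction, default 0.95.
#' @return integer number of components (at least 2).
#' @export
tica_dimension <- function(model, fraction = 0.95) {
  lam2 <- pmax(model$eigenvalues, 0)^2
  if (sum(lam2) == 0) return(2L)
  cum <- cumsum(lam2) / sum(lam2)
  max(2L, which(cum >= fraction)[1L])
}

#' k-means microstating in tICA space
#'
#' k-means++ seeding (deterministic under `seed`) followed by Lloyd
#' iterations. Empty clusters are pruned and labels renumbered densely.
#'
#' @param coords matrix or list of per-segment matrices of projected
#'   coordinates.
#' @param k number of microstates (default 150).
#' @param seed integer seed controlling initialization.
#' @param iter_max maximum Lloyd iterations (default 500).
#' @return `"microstate_model"`: list with `centers`, `dtrajs` (list of
#'   per-segment integer label vectors, 1..k), `k`, `seed`.
#' @export
kmeans_microstates <- function(coords, k = 150L, seed = 1L, iter_max = 500L) {
  segs <- as_segment_list(coords)
  X <- do.call(rbind, segs)
  if (nrow(X) < k) stopf("only %d frames for k = %d microstates", nrow(X), k)
  init <- kmeanspp_init(X, k, seed)
  km <- suppressWarnings(stats::kmeans(X, centers = init, iter.max = iter_max,
                                       algorithm = "Lloyd"))
  labels <- km$cluster
  centers <- km$centers
  occupied <- sort(unique(labels))
  if (length(occupied) < nrow(centers)) {
    centers <- centers[occupied, , drop = FALSE]
    labels <- match(labels, occupied)
  }
  lens <- vapply(segs, nrow, integer(1))
  idx <- split(seq_len(nrow(X)), rep(seq_along(segs), lens))
  dtrajs <- lapply(idx, function(i) labels[i])
  structure(list(centers = centers, dtrajs = unname(dtrajs),
                 k = nrow(centers), seed = seed),
            class = "microstate_model")
}

kmeanspp_init <- function(X, k, seed) {
  n <- nrow(X)
  set.seed(seed)
  centers <- matrix(NA_real_, k, ncol(X))
  i <- sample.int(n, 1L)
  centers[1L, ] <- X[i, ]
  d2 <- rowSums(sweep(X, 2L, centers[1L, ])^2)
  for (j in 2:k) {
    if (sum(d2) <= 0) i <- sample.int(n, 1L)
    else i <- sample.int(n, 1L, prob = d2)
    centers[j, ] <- X[i, ]
    d2 <- pmin(d2, rowSums(sweep(X, 2L, centers[j, ])^2))
  }
  centers
}

#' Sliding-window transition count matrix
#'
#' `C[i, j]` counts the transitions `s(t) = i, s(t + lag) = j` over all
#' segments (window slides one frame at a time).
#'
#' @param dtrajs integer vector or list of integer vectors (labels 1..n).
#' @param lag lag in frames.
#' @param n_states number of states (default: max observed label).
#' @return `n_states x n_states` count matrix.
#' @export
count_matrix <- function(dtrajs, lag, n_states = NULL) {
  if (!is.list(dtrajs)) dtrajs <- list(dtrajs)
  if (length(dtrajs) == 0L || all(vapply(dtrajs, length, 1L) == 0L))
    stopf("empty discrete trajectories")
  n_states <- n_states %||% max(unlist(dtrajs))
  C <- matrix(0, n_states, n_states)
  for (dt in dtrajs) {
    n <- length(dt)
    if (n <= lag) stopf("discrete trajectory of length %d too short for lag %d",
                        n, lag)
    from <- dt[seq_len(n - lag)]
    to <- dt[(lag + 1L):n]
    tab <- table(factor(from, levels = seq_len(n_states)),
                 factor(to, levels = seq_len(n_states)))
    C <- C + unclass(tab)
  }
  unname(C)
}

#' Estimate a Markov-state model from a count matrix
#'
#' Restricts to the largest strongly connected set of the count graph, then
#' estimates the transition matrix. The reversible maximum-likelihood
#' estimator enforces detailed balance via the standard self-consistent
#' fixed-point iteration; the non-reversible estimator is plain row
#' normalization (kept for testing). The stationary distribution follows
#' from the estimate.
#'
#' @param C non-negative count matrix.
#' @param lag lag (frames) the counts were taken at, stored for unit
#'   conversions.
#' @param reversible enforce detailed balance (default TRUE).
#' @param tol convergence tolerance on the maximum relative change
#'   (default 1e-10).
#' @param max_iter iteration cap.
#' @param frame_spacing optional ns per frame.
#' @return `"msm"`: list with `T` (row-stochastic), `pi`, `active`
#'   (original state indices kept), `fraction_states`, `fraction_counts`,
#'   `lag`, `reversible`, `frame_spacing`.
#' @export
estimate_msm <- function(C, lag = 1L, reversible = TRUE, tol = 1e-10,
                         max_iter = 10000L, frame_spacing = NULL) {
  C <- as.matrix(C)
  if (any(C < 0)) stopf("count matrix must be non-negative")
  n <- nrow(C)
  g <- igraph::graph_from_adjacency_matrix((C > 0) * 1, mode = "directed")
  comp <- igraph::components(g, mode = "strong")
  sizes <- tabulate(comp$membership)
  ## largest SCC by total counts, ties by size then lowest index
  totals <- vapply(seq_along(sizes), function(k) {
    idx <- which(comp$membership == k)
    sum(C[idx, idx])
  }, numeric(1))
  best <- which.max(totals + 1e-9 * sizes)
  active <- which(comp$membership == best)
  if (length(active) == 0L || sum(C[active, active]) == 0)
    stopf("empty connected set: no state has observed transitions")
  Ca <- C[active, active, drop = FALSE]
  if (reversible) {
    Tm <- reversible_mle(Ca, tol = tol, max_iter = max_iter)
  } else {
    rs <- rowSums(Ca)
    Tm <- Ca / rs
  }
  pi <- stationary_distribution(Tm)
  structure(list(T = Tm, pi = pi, active = active,
                 fraction_states = length(active) / n,
                 fraction_counts = sum(Ca) / max(sum(C), 1),
                 lag = lag, reversible = reversible,
                 frame_spacing = frame_spacing),
            class = "msm")
}

#' @export
print.msm <- function(x, ...) {
  cat(sprintf("MSM: %d states (%.0f%% of states, %.1f%% of counts), lag %d, %s\n",
              nrow(x$T), 100 * x$fraction_states, 100 * x$fraction_counts,
              x$lag, if (x$reversible) "reversible" else "non-reversible"))
  invisible(x)
}

## Reversible maximum-likelihood transition matrix (self-consistent
## fixed-point on the symmetric flux matrix x_ij).
reversible_mle <- function(C, tol = 1e-10, max_iter = 10000L) {
  S <- C + t(C)
  ci <- rowSums(C)
  x <- S / sum(S)
  nz <- S > 0
  for (it in seq_len(max_iter)) {
    xi <- rowSums(x)
    q <- ci / xi
    denom <- outer(q, q, `+`)
    xnew <- matrix(0, nrow(C), ncol(C))
    xnew[nz] <- S[nz] / denom[nz]
    xnew <- xnew / sum(xnew)
    delta <- max(abs(xnew - x) / pmax(x, 1e-300))
    x <- xnew
    if (delta < tol) break
  }
  xi <- rowSums(x)
  Tm <- x / xi
  Tm / rowSums(Tm)
}

#' Stationary distribution of a row-stochastic matrix
#'
#' @param T row-stochastic transition matrix.
#' @return probability vector `pi` with `pi T = pi`.
#' @export
stationary_distribution <- function(T) {
  e <- eigen(t(T))
  i <- which.min(abs(e$values - 1))
  v <- abs(Re(e$vectors[, i]))
  v / sum(v)
}

## Real sorted eigen-decomposition of a reversible T via the similarity
## transform D^{1/2} T D^{-1/2} (symmetric for detailed-balance T).
reversible_eigen <- function(T, pi = NULL) {
  pi <- pi %||% stationary_distribution(T)
  if (any(pi <= 0) || any(!is.finite(pi))) {
    ## degenerate stationary vector (e.g. reducible T): plain eigen fallback
    e <- eigen(T)
    ord <- order(Re(e$values), decreasing = TRUE)
    return(list(values = Re(e$values)[ord],
                vectors = Re(e$vectors)[, ord, drop = FALSE], pi = pi))
  }
  s <- sqrt(pi)
  Sym <- (T * outer(s, 1 / s))
  Sym <- (Sym + t(Sym)) / 2
  e <- eigen(Sym, symmetric = TRUE)
  vectors <- e$vectors / s      # right eigenvectors of T
  list(values = e$values, vectors = vectors, pi = pi)
}

#' Implied relaxation timescales of an MSM
#'
#' `t_i = -lag / log(lambda_{i+1})` for the sorted eigenvalue spectrum.
#' Non-positive eigenvalues are below the resolution of the lag and are
#' returned as `NA` with a warning. Output in frames, plus ns when the
#' model carries a frame spacing.
#'
#' @param msm an [estimate_msm()] model (or a row-stochastic matrix).
#' @param lag lag in frames when a bare matrix is given.
#' @param n number of timescales (default: all available).
#' @return data.frame with `index`, `eigenvalue`, `frames`, optionally `ns`.
#' @export
implied_timescales <- function(msm, lag = NULL, n = NULL) {
  if (is.matrix(msm)) {
    T <- msm; lag <- lag %||% 1L; fs <- NULL
  } else {
    T <- msm$T; lag <- lag %||% msm$lag; fs <- msm$frame_spacing
  }
  ev <- reversible_eigen(T)$values
  ev <- sort(ev, decreasing = TRUE)
  lams <- ev[-1L]
  if (!is.null(n)) lams <- lams[seq_len(min(n, length(lams)))]
  ts <- rep(NA_real_, length(lams))
  ok <- lams > 0 & lams < 1
  ts[ok] <- -lag / log(lams[ok])
  ts[lams >= 1] <- Inf
  if (any(lams <= 0))
    warning("some eigenvalues are non-positive: timescales below lag resolution set to NA")
  out <- data.frame(index = seq_along(lams) + 1L, eigenvalue = lams,
                    frames = ts)
  if (!is.null(fs)) out$ns <- ts * fs
  out
}

#' Implied timescales across a range of lags
#'
#' Convenience scan used to check lag-independence (Markovianity) of the
#' leading timescales.
#'
#' @param dtrajs discrete trajectories.
#' @param lags integer vector of lags (frames).
#' @param n_timescales how many timescales to record.
#' @param n_states number of states.
#' @return data.frame with columns `lag`, `index`, `frames`.
#' @export
its_scan <- function(dtrajs, lags, n_timescales = 3L, n_states = NULL) {
  out <- list()
  for (lg in lags) {
    m <- estimate_msm(count_matrix(dtrajs, lg, n_states), lag = lg)
    it <- implied_timescales(m, n = n_timescales)
    out[[length(out) + 1L]] <- data.frame(lag = lg, index = it$index,
                                          frames = it$frames)
  }
  do.call(rbind, out)
}

#' PCCA+ metastable coarse-graining
#'
#' Fuzzy decomposition of the microstates into m metastable macrostates from
#' the leading m eigenvectors of the reversible transition matrix: the
#' eigenvector rows span an (m-1)-simplex whose vertices are located by the
#' inner-simplex vertex search; memberships chi are the barycentric
#' coordinates, clipped to the feasible set and renormalized. Crisp labels
#' are the argmax memberships; macrostate probabilities aggregate the
#' stationary distribution.
#'
#' @param msm an [estimate_msm()] model.
#' @param m number of macrostates (>= 2, at most the number of positive
#'   leading eigenvalues).
#' @return `"pcca"`: list with `memberships` (microstates x m), `crisp`
#'   (1..m per microstate), `probabilities` (length m), `m`.
#' @export
pcca_plus <- function(msm, m) {
  if (m < 2L) stopf("m must be at least 2")
  ed <- reversible_eigen(msm$T, msm$pi)
  npos <- sum(ed$values > 1e-12)
  if (m > npos)
    stopf("m = %d exceeds the number of positive leading eigenvalues (%d); choose a smaller m",
          m, npos)
  if (m > nrow(msm$T)) stopf("m cannot exceed the number of microstates")
  X <- ed$vectors[, seq_len(m), drop = FALSE]
  ## normalize the first (stationary) eigenvector to exactly 1
  X[, 1L] <- 1
  ## inner-simplex vertex search: greedily pick the row farthest from the
  ## affine span of the vertices found so far
  ind <- integer(m)
  ind[1L] <- which.max(rowSums(X^2))
  Y <- sweep(X, 2L, X[ind[1L], ])
  for (k in seq_len(m - 1L) + 1L) {
    d <- rowSums(Y^2)
    d[ind[seq_len(k - 1L)]] <- -1
    ind[k] <- which.max(d)
    if (k < m) {
      v <- Y[ind[k], ]
      v <- v / sqrt(sum(v^2))
      Y <- Y - outer(drop(Y %*% v), v)
    }
  }
  A <- solve(X[ind, , drop = FALSE])
  chi <- X %*% A
  chi[chi < 0] <- 0
  chi <- chi / rowSums(chi)
  crisp <- max.col(chi, ties.method = "first")
  probs <- drop(crossprod(chi, msm$pi))
  probs <- probs / sum(probs)
  structure(list(memberships = chi, crisp = crisp, probabilities = probs,
                 m = m, vertices = ind),
            class = "pcca")
}

#' @export
print.pcca <- function(x, ...) {
  cat(sprintf("PCCA+ coarse-graining into %d macrostates\n", x$m))
  cat("probabilities:", paste(sprintf("%.3f", x$probabilities),
                              collapse = " "), "\n")
  invisible(x)
}

## MFPT (in steps of the transition matrix) into a target state set.
mfpt_to_set <- function(T, target) {
  n <- nrow(T)
  src <- setdiff(seq_len(n), target)
  h <- numeric(n)
  if (length(src)) {
    A <- diag(length(src)) - T[src, src, drop = FALSE]
    b <- rep(1, length(src))
    sol <- tryCatch(solve(A, b), error = function(e) rep(Inf, length(src)))
    h[src] <- sol
  }
  h
}

#' Macrostate kinetics: mean first-passage times and probabilities
#'
#' Pairwise MFPTs between PCCA+ macrostates by first-step analysis on the
#' microstate transition matrix (linear solve), with the source-state
#' average weighted by the stationary distribution restricted to the source
#' macrostate. Times are reported in frames (steps x lag) and in ns when a
#' frame spacing is available. Unreachable pairs yield `Inf`.
#'
#' @param msm an [estimate_msm()] model.
#' @param macro a [pcca_plus()] object.
#' @return `"macro_kinetics"`: list with `mfpt_frames` (m x m), optionally
#'   `mfpt_ns`, and `probabilities`.
#' @export
macrostate_kinetics <- function(msm, macro) {
  m <- macro$m
  M <- matrix(0, m, m)
  for (b in seq_len(m)) {
    target <- which(macro$crisp == b)
    h <- mfpt_to_set(msm$T, target)
    for (a in seq_len(m)) {
      if (a == b) next
      src <- which(macro$crisp == a)
      w <- msm$pi[src]
      M[a, b] <- sum(w * h[src]) / sum(w)
    }
  }
  M[!is.finite(M)] <- Inf
  out <- list(mfpt_frames = M * msm$lag, probabilities = macro$probabilities)
  if (!is.null(msm$frame_spacing)) out$mfpt_ns <- out$mfpt_frames * msm$frame_spacing
  structure(out, class = "macro_kinetics")
}

## Coarse-grained set-to-set transition probabilities of T under pi.
setwise_transition <- function(T, pi, sets) {
  m <- length(sets)
  P <- matrix(0, m, m)
  for (a in seq_len(m)) {
    wa <- pi[sets[[a]]]
    if (sum(wa) == 0) next
    for (b in seq_len(m)) {
      P[a, b] <- sum(wa * rowSums(T[sets[[a]], sets[[b]], drop = FALSE])) / sum(wa)
    }
  }
  P
}

#' Chapman-Kolmogorov test
#'
#' Validates Markovianity on the macrostate level: compares the propagated
#' base model, `T(lag)^k`, against models re-estimated at lag `k * lag`,
#' coarse-grained onto the same PCCA+ macrostate sets, for
#' `k in multiples`. Error bars are multinomial standard errors
#' `sqrt(p (1 - p) / N_a)` with `N_a` the transition counts leaving set a
#' at the longer lag.
#'
#' @param dtrajs discrete trajectories (1..n_states labels).
#' @param lag base lag in frames.
#' @param n_macrostates number of PCCA+ macrostates to test.
#' @param multiples lag multiples (default 1:5).
#' @param n_states number of microstates.
#' @return `"ck_test"`: list with arrays `predicted`, `estimated`,
#'   `se` (`length(multiples) x m x m`), `multiples`, and
#'   `max_deviation` per multiple.
#' @export
ck_test <- function(dtrajs, lag, n_macrostates, multiples = 1:5,
                    n_states = NULL) {
  if (!is.list(dtrajs)) dtrajs <- list(dtrajs)
  n_states <- n_states %||% max(unlist(dtrajs))
  maxlag <- lag * max(multiples)
  if (all(vapply(dtrajs, length, 1L) <= maxlag))
    stopf("trajectories too short for lag multiple %d", max(multiples))
  base <- estimate_msm(count_matrix(dtrajs, lag, n_states), lag = lag)
  macro <- pcca_plus(base, n_macrostates)
  m <- n_macrostates
  ## macrostate sets in original (pre-restriction) state indices
  sets_orig <- lapply(seq_len(m), function(a) base$active[macro$crisp == a])
  nm <- length(multiples)
  pred <- est <- se <- array(NA_real_, dim = c(nm, m, m))
  maxdev <- numeric(nm)
  for (ki in seq_along(multiples)) {
    k <- multiples[ki]
    Tk <- base$T
    if (k > 1L) for (i in seq_len(k - 1L)) Tk <- Tk %*% base$T
    sets_base <- lapply(seq_len(m), function(a) which(macro$crisp == a))
    pred[ki, , ] <- setwise_transition(Tk, base$pi, sets_base)
    Ck <- count_matrix(dtrajs, lag * k, n_states)
    mk <- estimate_msm(Ck, lag = lag * k)
    sets_k <- lapply(sets_orig, function(s) match(intersect(s, mk$active),
                                                  mk$active))
    if (any(vapply(sets_k, length, 1L) == 0L)) {
      maxdev[ki] <- NA_real_
      next
    }
    est[ki, , ] <- setwise_transition(mk$T, mk$pi, sets_k)
    for (a in seq_len(m)) {
      Na <- sum(Ck[unlist(sets_orig[a]), , drop = FALSE])
      p <- est[ki, a, ]
      se[ki, a, ] <- sqrt(pmax(p * (1 - p), 0) / max(Na, 1))
    }
    maxdev[ki] <- max(abs(pred[ki, , ] - est[ki, , ]))
  }
  structure(list(predicted = pred, estimated = est, se = se,
                 multiples = multiples, max_deviation = maxdev,
                 n_macrostates = m),
            class = "ck_test")
}

#' @export
print.ck_test <- function(x, ...) {
  cat(sprintf("Chapman-Kolmogorov test (%d macrostates):\n", x$n_macrostates))
  for (i in seq_along(x$multiples))
    cat(sprintf("  lag x%-2d max |predicted - estimated| = %.4f\n",
                x$multiples[i], x$max_deviation[i]))
  invisible(x)
}

#' Free-energy surface from sampled coordinates
#'
#' Histograms samples on a 1D or 2D grid and converts occupation
#' probabilities to free energies `dG = -kB T ln(p / p_max)` in kcal/mol,
#' so the most populated bin sits at exactly zero. Empty bins carry `NA`.
#'
#' @param coords numeric vector, or matrix with 1 or 2 columns.
#' @param bins number of bins per axis (scalar or length-2).
#' @param weights optional per-sample weights.
#' @param temperature Kelvin, default 300.
#' @param limits optional list of per-axis c(lo, hi) ranges.
#' @return `"fes"`: list with `G` (matrix bins_x x bins_y, or vector),
#'   `p`, `xedges`, `yedges` (NULL in 1D), `kT` (kcal/mol), `temperature`.
#' @export
free_energy_surface <- function(coords, bins = 40L, weights = NULL,
                                temperature = 300, limits = NULL) {
  if (is.null(dim(coords))) coords <- matrix(coords, ncol = 1L)
  coords <- as.matrix(coords)
  if (nrow(coords) == 0L) stopf("empty input")
  ndim <- ncol(coords)
  if (!ndim %in% c(1L, 2L)) stopf("free_energy_surface supports 1 or 2 coordinates")
  if (length(bins) == 1L) bins <- rep(bins, ndim)
  weights <- weights %||% rep(1, nrow(coords))
  kT <- .kB_kcal * temperature
  edges <- lapply(seq_len(ndim), function(d) {
    lim <- if (!is.null(limits)) limits[[d]] else range(coords[, d])
    if (diff(lim) == 0) lim <- lim + c(-0.5, 0.5)
    seq(lim[1L], lim[2L], length.out = bins[d] + 1L)
  })
  bin_of <- function(x, e) {
    b <- findInterval(x, e, rightmost.closed = TRUE)
    b[b < 1L | b > length(e) - 1L] <- NA_integer_
    b
  }
  bx <- bin_of(coords[, 1L], edges[[1L]])
  if (ndim == 2L) {
    by <- bin_of(coords[, 2L], edges[[2L]])
    ok <- !is.na(bx) & !is.na(by)
    p <- matrix(0, bins[1L], bins[2L])
    tab <- tapply(weights[ok], list(factor(bx[ok], levels = seq_len(bins[1])),
                                    factor(by[ok], levels = seq_len(bins[2]))),
                  sum)
    tab[is.na(tab)] <- 0
    p[] <- tab
  } else {
    ok <- !is.na(bx)
    p <- as.numeric(tapply(weights[ok], factor(bx[ok], levels = seq_len(bins[1])),
                           sum))
    p[is.na(p)] <- 0
  }
  if (sum(p) == 0) stopf("no occupied bins")
  p <- p / sum(p)
  G <- -kT * log(p / max(p))
  G[p == 0] <- NA_real_
  structure(list(G = G, p = p, xedges = edges[[1L]],
                 yedges = if (ndim == 2L) edges[[2L]] else NULL,
                 kT = kT, temperature = temperature),
            class = "fes")
}

#' Export a free-energy surface as a dense grid table
#'
#' @param fes a [free_energy_surface()] result.
#' @param file CSV path.
#' @return `file`, invisibly.
#' @export
export_fes <- function(fes, file) {
  mid <- function(e) (e[-1L] + e[-length(e)]) / 2
  if (is.null(fes$yedges)) {
    df <- data.frame(x = mid(fes$xedges), p = fes$p, G = fes$G)
  } else {
    xm <- mid(fes$xedges); ym <- mid(fes$yedges)
    df <- expand.grid(x = xm, y = ym)
    df$p <- as.vector(fes$p)
    df$G <- as.vector(fes$G)
  }
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}
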