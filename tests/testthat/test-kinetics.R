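ar1 <- function(phi, n) {
  x <- numeric(n)
  e <- rnorm(n, sd = sqrt(1 - phi^2))
  for (t in 2:n) x[t] <- phi * x[t - 1] + e[t]
  x
}

test_that("tICA separates a slow from a fast AR(1) mode", {
  set.seed(31)
  n <- 1e5
  X <- cbind(ar1(0.99, n), ar1(0.50, n))
  tm <- fit_tica(X, lag = 1)
  v1 <- tm$eigenvectors[, 1]
  align <- abs(v1[1]) / sqrt(sum(v1^2))
  expect_gt(align, 0.99)
  expect_equal(tm$eigenvalues[1], 0.99, tolerance = 0.02)
  # eigenvectors are C0-orthonormal
  G <- t(tm$eigenvectors) %*% (tm$C0 + diag(tm$ridge, 2)) %*% tm$eigenvectors
  expect_equal(G, diag(2), tolerance = 1e-8, ignore_attr = TRUE)
  # white noise has no slow modes
  W <- matrix(rnorm(2 * n), ncol = 2)
  tw <- fit_tica(W, lag = 1)
  expect_true(all(abs(tw$eigenvalues) < 3 / sqrt(n)))
})

test_that("duplicated feature columns are absorbed by the ridge", {
  set.seed(32)
  n <- 2e4
  X <- cbind(ar1(0.95, n), ar1(0.3, n))
  tm1 <- fit_tica(X, lag = 2)
  tm2 <- fit_tica(cbind(X, X[, 1]), lag = 2)
  expect_equal(tm1$eigenvalues[1:2], tm2$eigenvalues[1:2], tolerance = 1e-4)
  expect_error(fit_tica(X[1:2, ], lag = 5), "shorter than lag")
})

test_that("tICA projection is mean-free, unit-variance, and brute-force exact", {
  set.seed(33)
  n <- 5e4
  X <- cbind(ar1(0.9, n), ar1(0.6, n), ar1(0.2, n))
  tm <- fit_tica(X, lag = 5)
  Y <- project_tica(tm, X)
  # projecting the training mean gives the origin
  expect_equal(as.numeric(project_tica(tm, matrix(tm$mean, 1))),
               rep(0, 3), tolerance = 1e-12)
  expect_equal(apply(Y, 2, var), rep(1, 3), tolerance = 0.05,
               ignore_attr = TRUE)
  # brute force on random rows
  rows <- sample(n, 20)
  bf <- sweep(X[rows, ], 2, tm$mean) %*% tm$eigenvectors
  expect_equal(Y[rows, ], bf, tolerance = 1e-12)
  expect_error(project_tica(tm, X[, 1:2]), "dimensionality")
})

test_that("k-means microstating is deterministic and separates blobs", {
  set.seed(34)
  blobs <- rbind(matrix(rnorm(200, 0, 0.3), ncol = 2),
                 matrix(rnorm(200, 6, 0.3), ncol = 2),
                 matrix(rnorm(200, c(0, 12), 0.3), ncol = 2, byrow = TRUE))
  truth <- rep(1:3, each = 100)
  km <- kmeans_microstates(blobs, k = 3, seed = 5)
  expect_true(same_partition(km$dtrajs[[1]], truth))
  km2 <- kmeans_microstates(blobs, k = 3, seed = 5)
  expect_identical(km$dtrajs, km2$dtrajs)  # bit-identical under fixed seed
  # k = n gives zero inertia (every point its own center)
  small <- blobs[1:8, ]
  km3 <- kmeans_microstates(small, k = 8, seed = 1)
  expect_equal(sort(km3$dtrajs[[1]]), 1:8)
  expect_error(kmeans_microstates(small, k = 20, seed = 1), "frames")
})

test_that("count matrix matches hand counts and a brute-force loop", {
  expect_equal(count_matrix(c(1, 1, 2, 2, 1), lag = 1),
               matrix(c(1, 1, 1, 1), 2, 2))
  expect_equal(sum(count_matrix(c(1, 2, 1, 2, 2), lag = 4)), 1)
  set.seed(35)
  dt <- sample(1:4, 300, replace = TRUE)
  C <- count_matrix(dt, lag = 3, n_states = 4)
  bf <- matrix(0, 4, 4)
  for (t in 1:(300 - 3)) bf[dt[t], dt[t + 3]] <- bf[dt[t], dt[t + 3]] + 1
  expect_equal(C, bf)
  # segments never contribute cross-boundary pairs
  C2 <- count_matrix(list(dt[1:150], dt[151:300]), lag = 3, n_states = 4)
  expect_equal(sum(C2), 2 * (150 - 3))
  expect_error(count_matrix(integer(0), 1), "empty")
})

test_that("MSM estimation: closed form, connectivity, detailed balance, MLE", {
  m <- estimate_msm(matrix(c(9, 1, 1, 9), 2, 2), lag = 1)
  expect_equal(m$T, matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2), tolerance = 1e-9)
  expect_equal(m$pi, c(0.5, 0.5), tolerance = 1e-9)
  # block-diagonal counts: the bigger block is kept
  Cb <- matrix(0, 4, 4)
  Cb[1:2, 1:2] <- matrix(c(5, 1, 1, 5), 2, 2)
  Cb[3:4, 3:4] <- matrix(c(50, 10, 10, 50), 2, 2)
  mb <- estimate_msm(Cb, lag = 1)
  expect_identical(mb$active, 3:4)
  expect_lt(mb$fraction_counts, 1)
  # random connected counts: stochasticity, stationarity, detailed balance
  set.seed(36)
  C <- matrix(rpois(25, 20) + 1, 5, 5)
  mr <- estimate_msm(C, lag = 1)
  expect_equal(rowSums(mr$T), rep(1, 5), tolerance = 1e-12)
  expect_equal(drop(mr$pi %*% mr$T), mr$pi, tolerance = 1e-10)
  db <- outer(mr$pi, rep(1, 5)) * mr$T
  expect_equal(db, t(db), tolerance = 1e-8)
  # the reversible estimate maximizes the likelihood among detailed-balance
  # models: random reversible perturbations never score higher
  loglik <- function(T) sum(C[T > 0] * log(T[T > 0]))
  l0 <- loglik(mr$T)
  for (i in 1:20) {
    x <- db * exp(matrix(rnorm(25, sd = 0.05), 5, 5))
    x <- (x + t(x)) / 2
    Tp <- x / rowSums(x)
    expect_lte(loglik(Tp), l0 + 1e-9)
  }
  # non-reversible mode is plain row normalization
  mn <- estimate_msm(C, lag = 1, reversible = FALSE)
  expect_equal(mn$T, C / rowSums(C), tolerance = 1e-12)
})

test_that("implied timescales match closed forms and flag degenerate spectra", {
  T2 <- matrix(c(0.95, 0.05, 0.05, 0.95), 2, 2)
  it <- implied_timescales(T2, lag = 1)
  expect_equal(it$frames, -1 / log(0.9), tolerance = 1e-10)
  it3 <- implied_timescales(T2, lag = 3)
  expect_equal(it3$frames, -3 / log(0.9), tolerance = 1e-10)
  expect_true(is.infinite(implied_timescales(diag(2), lag = 1)$frames))
  Tn <- matrix(c(0.2, 0.8, 0.8, 0.2), 2, 2)
  expect_warning(itn <- implied_timescales(Tn, lag = 1), "non-positive")
  expect_true(is.na(itn$frames))
})

test_that("timescales of a synthetic chain are recovered and lag-independent", {
  set.seed(37)
  T_true <- matrix(c(0.97, 0.02, 0.01,
                     0.02, 0.96, 0.02,
                     0.01, 0.03, 0.96), 3, 3, byrow = TRUE)
  path <- sample_markov_chain(T_true, 1e5)
  ev <- sort(Re(eigen(T_true)$values), decreasing = TRUE)
  for (lg in c(1, 5)) {
    m <- estimate_msm(count_matrix(path, lg), lag = lg)
    it <- implied_timescales(m, n = 2)
    expect_equal(it$frames[1], -1 / log(ev[2]), tolerance = 0.15)
    expect_equal(it$frames[2], -1 / log(ev[3]), tolerance = 0.15)
  }
  scan <- its_scan(path, lags = c(1, 2, 5, 10), n_timescales = 1)
  expect_lt(diff(range(scan$frames)) / mean(scan$frames), 0.15)
})

test_that("PCCA+ recovers metastable blocks with crisp memberships", {
  # 2-block, 4-microstate chain
  T4 <- matrix(c(0.89, 0.10, 0.005, 0.005,
                 0.10, 0.89, 0.005, 0.005,
                 0.005, 0.005, 0.89, 0.10,
                 0.005, 0.005, 0.10, 0.89), 4, 4, byrow = TRUE)
  m4 <- structure(list(T = T4, pi = stationary_distribution(T4), lag = 1),
                  class = "msm")
  p <- pcca_plus(m4, 2)
  expect_equal(rowSums(p$memberships), rep(1, 4), tolerance = 1e-10)
  expect_true(all(p$memberships >= 0 & p$memberships <= 1))
  own <- p$memberships[cbind(1:4, p$crisp)]
  expect_true(all(own >= 0.99))
  expect_true(same_partition(p$crisp, c(1, 1, 2, 2)))
  expect_equal(sum(p$probabilities), 1, tolerance = 1e-10)
  # 3-block, 6-microstate chain: probabilities equal block stationary sums
  blocks <- rep(1:3, each = 2)
  T6 <- matrix(0.001, 6, 6)
  for (b in 1:3) {
    i <- which(blocks == b)
    T6[i, i] <- matrix(c(0, 0.15, 0.15, 0), 2, 2)
  }
  diag(T6) <- 0
  T6 <- T6 + diag(1 - rowSums(T6))
  pi6 <- stationary_distribution(T6)
  m6 <- structure(list(T = T6, pi = pi6, lag = 1), class = "msm")
  p6 <- pcca_plus(m6, 3)
  expect_true(same_partition(p6$crisp, blocks))
  blocksum <- tapply(pi6, blocks, sum)
  expect_equal(sort(as.numeric(p6$probabilities)), sort(as.numeric(blocksum)),
               tolerance = 1e-6)
  # m equal to the microstate count is the identity coarse-graining
  pid <- pcca_plus(m4, 4)
  expect_equal(sort(pid$crisp), 1:4)
  expect_error(pcca_plus(m4, 5), "smaller m|exceed")
})

test_that("macrostate kinetics reproduce closed-form and simulated MFPTs", {
  T2 <- matrix(c(0.9, 0.1, 0.05, 0.95), 2, 2, byrow = TRUE)
  m2 <- structure(list(T = T2, pi = stationary_distribution(T2), lag = 1),
                  class = "msm")
  macro2 <- structure(list(m = 2, crisp = 1:2,
                           probabilities = m2$pi), class = "pcca")
  k2 <- macrostate_kinetics(m2, macro2)
  expect_equal(k2$mfpt_frames[1, 2], 10, tolerance = 1e-10)
  expect_equal(k2$mfpt_frames[2, 1], 20, tolerance = 1e-10)
  expect_equal(m2$pi, c(1, 2) / 3, tolerance = 1e-9)
  # symmetric chain: symmetric MFPTs
  Ts <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2)
  ms <- structure(list(T = Ts, pi = c(0.5, 0.5), lag = 1), class = "msm")
  ks <- macrostate_kinetics(ms, structure(list(m = 2, crisp = 1:2,
                                               probabilities = c(0.5, 0.5)),
                                          class = "pcca"))
  expect_equal(ks$mfpt_frames[1, 2], ks$mfpt_frames[2, 1])
  # 3-block chain versus a long direct simulation
  set.seed(38)
  blocks <- rep(1:3, each = 2)
  T6 <- matrix(0.002, 6, 6)
  for (b in 1:3) {
    i <- which(blocks == b)
    T6[i, i] <- matrix(c(0, 0.2, 0.2, 0), 2, 2)
  }
  diag(T6) <- 0
  T6 <- T6 + diag(1 - rowSums(T6))
  m6 <- structure(list(T = T6, pi = stationary_distribution(T6), lag = 1),
                  class = "msm")
  p6 <- structure(list(m = 3, crisp = blocks,
                       probabilities = tapply(m6$pi, blocks, sum)),
                  class = "pcca")
  k6 <- macrostate_kinetics(m6, p6)
  path <- sample_markov_chain(T6, 1e6)
  for (a in 1:2) for (b in (a + 1):3) {
    emp <- empirical_mfpt(path, which(blocks == a), which(blocks == b))
    expect_equal(k6$mfpt_frames[a, b], emp, tolerance = 0.05)
  }
  # unreachable pair
  Td <- diag(2)
  md <- structure(list(T = Td, pi = c(0.5, 0.5), lag = 1), class = "msm")
  kd <- macrostate_kinetics(md, structure(list(m = 2, crisp = 1:2,
                                               probabilities = c(0.5, 0.5)),
                                          class = "pcca"))
  expect_true(is.infinite(kd$mfpt_frames[1, 2]))
})

test_that("Chapman-Kolmogorov test validates Markov data and flags violations", {
  set.seed(39)
  T4 <- matrix(c(0.95, 0.03, 0.01, 0.01,
                 0.03, 0.95, 0.01, 0.01,
                 0.01, 0.01, 0.95, 0.03,
                 0.01, 0.01, 0.03, 0.95), 4, 4, byrow = TRUE)
  path <- sample_markov_chain(T4, 5e4)
  ck <- ck_test(path, lag = 1, n_macrostates = 2, multiples = 1:5)
  # m = 1 is the identity case
  expect_equal(ck$predicted[1, , ], ck$estimated[1, , ], tolerance = 1e-9)
  # Markovian by construction: deviations within a few sampling errors
  for (ki in 2:5) {
    expect_lt(ck$max_deviation[ki],
              max(5 * ck$se[ki, , ], 0.02))
  }
  # non-Markovian observation: 3-state chain seen through 2 coarse states;
  # the hidden superstate mixes a fast-return substate with a deep trap, so
  # observed dwell times are strongly non-exponential
  T3 <- matrix(c(0.98, 0.02, 0.00,
                 0.30, 0.60, 0.10,
                 0.00, 0.01, 0.99), 3, 3, byrow = TRUE)
  path3 <- sample_markov_chain(T3, 2e5)
  obs <- ifelse(path3 == 1, 1, 2)
  ck_bad <- ck_test(obs, lag = 1, n_macrostates = 2, multiples = c(1, 10, 25))
  expect_gt(ck_bad$max_deviation[3], 5 * max(ck_bad$se[3, , ]))
  expect_error(ck_test(obs[1:20], lag = 1, n_macrostates = 2,
                       multiples = c(1, 50)), "too short")
})

test_that("free-energy surfaces follow the Boltzmann inversion closed forms", {
  # uniform samples inside one bin
  f1 <- free_energy_surface(cbind(runif(100, 0.1, 0.2), runif(100, 0.1, 0.2)),
                            bins = 2, limits = list(c(0, 1), c(0, 1)))
  expect_equal(sum(f1$p > 0), 1)
  expect_equal(min(f1$G, na.rm = TRUE), 0)
  # two bins with probability ratio e^-1 differ by exactly kT
  x <- c(rep(0.25, 2718), rep(0.75, 1000))
  f2 <- free_energy_surface(x, bins = 2, limits = list(c(0, 1)))
  kT <- 0.0019872041 * 300
  expect_equal(f2$G[2] - f2$G[1], kT * log(2718 / 1000), tolerance = 1e-9)
  expect_equal(f2$G[2] - f2$G[1], kT, tolerance = 1e-3)
  # occupied-bin minimum is exactly zero; probabilities renormalize
  set.seed(40)
  f3 <- free_energy_surface(matrix(rnorm(2000), ncol = 2), bins = 11)
  expect_equal(min(f3$G, na.rm = TRUE), 0)
  expect_equal(sum(f3$p), 1, tolerance = 1e-12)
  expect_error(free_energy_surface(numeric(0)), "empty")
})

test_that("double-well barrier is recovered from the sampled surface", {
  dw <- simulate_double_well(2, n_steps = 2e5, seed = 41)
  f <- free_energy_surface(dw$samples[, 1], bins = 51)
  mid <- (f$xedges[-1] + f$xedges[-length(f$xedges)]) / 2
  barrier <- f$G[which.min(abs(mid))]
  expect_equal(barrier, 2, tolerance = 0.15)
})
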