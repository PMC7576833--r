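# A small end-to-end fixture shared by the synthesis-stage tests: a short
# hidden-Markov torsion simulation pushed through featurization, tICA,
# microstating and the MSM.
make_pipeline_fixture <- function(n_frames = 8000, seed = 51) {
  spec <- default_hmm_fixture(n_frames = n_frames, seed = seed)
  sim <- simulate_hmm_torsions(spec)
  coupled <- names(which(vapply(spec$loops, function(l) isTRUE(l$coupled),
                                logical(1))))
  feats <- do.call(cbind, lapply(sim$torsions[coupled], sincos_features))
  tm <- fit_tica(feats, lag = 5)
  Y <- project_tica(tm, feats, n_components = 6)
  micro <- kmeans_microstates(Y, k = 60, seed = seed)
  msm <- estimate_msm(count_matrix(micro$dtrajs, 5), lag = 5)
  macro <- pcca_plus(msm, 4)
  list(spec = spec, sim = sim, feats = feats, tica = tm, Y = Y,
       micro = micro, msm = msm, macro = macro)
}

test_that("macrostate ensembles partition frames and track hidden occupancies", {
  fx <- make_pipeline_fixture()
  ens <- macrostate_ensembles(fx$micro, fx$msm, fx$macro, coords = fx$Y)
  all_frames <- sort(c(unlist(lapply(ens, `[[`, "frames")),
                       attr(ens, "unassigned")))
  expect_identical(all_frames, seq_len(fx$spec$n_frames))
  expect_equal(sum(vapply(ens, `[[`, numeric(1), "probability")), 1,
               tolerance = 1e-9)
  # ensemble occupancies track the hidden-state occupancies
  occ_hidden <- sort(tabulate(fx$sim$hidden, 4) / fx$spec$n_frames)
  occ_ens <- sort(vapply(ens, function(e) length(e$frames), numeric(1)) /
                    fx$spec$n_frames)
  expect_equal(occ_ens, occ_hidden, tolerance = 0.03)
  # representatives live inside their own ensemble
  for (e in ens) expect_true(e$representative %in% e$frames)
})

test_that("hand-built macrostate partition matches the hand count", {
  micro <- structure(list(dtrajs = list(c(1L, 1L, 2L, 2L, 1L, 2L)),
                          centers = matrix(c(0, 1), 2, 1), k = 2, seed = 1),
                     class = "microstate_model")
  msm <- structure(list(T = matrix(c(.9, .1, .1, .9), 2, 2),
                        pi = c(0.5, 0.5), active = 1:2, lag = 1),
                   class = "msm")
  macro <- structure(list(m = 2, crisp = 1:2, probabilities = c(0.5, 0.5),
                          memberships = diag(2)), class = "pcca")
  ens <- macrostate_ensembles(micro, msm, macro)
  expect_identical(ens[[1]]$frames, c(1L, 2L, 5L))
  expect_identical(ens[[2]]$frames, c(3L, 4L, 6L))
})

test_that("per-state angle distributions recover a prescribed median shift", {
  fx <- make_pipeline_fixture()
  ens <- macrostate_ensembles(fx$micro, fx$msm, fx$macro, coords = fx$Y)
  # synthetic interface angle: hidden-state-dependent mean, +5 degrees per state
  set.seed(52)
  means <- c(40, 45, 50, 55)
  angles <- means[fx$sim$hidden] + rnorm(fx$spec$n_frames, sd = 1)
  d <- per_state_angle_distribution(ens, angles, breaks = 360)
  expect_equal(nrow(d$summary), 4)
  # states map to hidden states up to relabeling: sorted medians are 5 apart
  med <- sort(d$summary$median)
  expect_equal(diff(med), rep(5, 3), tolerance = 0.5)
  # concatenating the per-state histograms reproduces the total histogram
  tot <- hist(paratopeMSM:::wrap_angle(angles), breaks = d$breaks,
              plot = FALSE)$counts
  acc <- Reduce(`+`, d$histograms)
  expect_equal(acc, tot)
  # single macrostate equals the whole-trajectory histogram
  ens1 <- structure(list(list(id = 1, frames = seq_along(angles),
                              probability = 1, representative = 1L)),
                    class = "macrostate_ensembles", unassigned = integer(0))
  d1 <- per_state_angle_distribution(ens1, angles, breaks = 360)
  expect_equal(d1$histograms[["1"]], tot)
  expect_error(per_state_angle_distribution(ens, angles[1:10]), "shorter")
})

test_that("macrostate representatives project into occupied loop-surface bins", {
  fx <- make_pipeline_fixture()
  ens <- macrostate_ensembles(fx$micro, fx$msm, fx$macro, coords = fx$Y)
  loop_feats <- sincos_features(fx$sim$torsions$CDR_L1)
  loop_tica <- fit_tica(loop_feats, lag = 5)
  proj <- project_macrostates_on_loop_fes(loop_tica, loop_feats, ens)
  expect_equal(nrow(proj), 4)
  # brute-force projection of the representative frames
  Yl <- project_tica(loop_tica, loop_feats, n_components = 2)
  for (i in seq_len(nrow(proj))) {
    expect_equal(c(proj$tIC1[i], proj$tIC2[i]),
                 as.numeric(Yl[proj$frame[i], ]), tolerance = 1e-12)
  }
  # representatives land in occupied bins of the loop surface
  fes <- free_energy_surface(Yl, bins = 30)
  for (i in seq_len(nrow(proj))) {
    bx <- findInterval(proj$tIC1[i], fes$xedges, rightmost.closed = TRUE)
    by <- findInterval(proj$tIC2[i], fes$yedges, rightmost.closed = TRUE)
    expect_false(is.na(fes$G[bx, by]))
  }
})

test_that("co-occurrence marginals are exact and Cramer's V matches brute force", {
  set.seed(53)
  la <- sample(1:3, 500, replace = TRUE)
  lb <- sample(1:4, 500, replace = TRUE)
  cla <- structure(list(labels = la, k = 3), class = "cluster_result")
  clb <- structure(list(labels = lb, k = 4), class = "cluster_result")
  clc <- structure(list(labels = la, k = 3), class = "cluster_result")
  cooc <- loop_cooccurrence(list(A = cla, B = clb, C = clc))
  tab <- cooc$tables[["A|B"]]
  expect_equal(sum(tab), 500)
  expect_equal(as.numeric(rowSums(tab)), as.numeric(table(la)))
  expect_equal(as.numeric(colSums(tab)), as.numeric(table(lb)))
  # identical labels: perfect association
  vAC <- cooc$pairs$cramers_v[cooc$pairs$loop_a == "A" &
                                cooc$pairs$loop_b == "C"]
  expect_equal(vAC, 1, tolerance = 1e-10)
  # independent labels at n large: near zero
  set.seed(54)
  li <- sample(1:3, 1e4, replace = TRUE)
  lj <- sample(1:3, 1e4, replace = TRUE)
  expect_lt(cramers_v(li, lj), 0.05)
  # brute-force chi-squared agreement
  expect_equal(cramers_v(la, lb), bf_cramers_v(la, lb), tolerance = 1e-10)
  expect_error(loop_cooccurrence(list(A = cla)), "at least two")
  short <- structure(list(labels = la[1:100], k = 3), class = "cluster_result")
  expect_error(loop_cooccurrence(list(A = cla, B = short)), "different frame")
})

test_that("coupled loops score higher association than the decoupled loop", {
  spec <- default_hmm_fixture(n_frames = 20000, seed = 55)
  sim <- simulate_hmm_torsions(spec)
  # cluster each loop's torsions by average linkage on circular distance
  sub <- seq(1, spec$n_frames, by = 50)   # 400-frame subsample
  cls <- list()
  for (nm in names(sim$torsions)) {
    v <- unclass(sim$torsions[[nm]])[sub, ]
    D <- matrix(0, length(sub), length(sub))
    for (d in seq_len(ncol(v))) {
      dd <- abs(outer(v[, d], v[, d], `-`)) %% 360
      D <- D + pmin(dd, 360 - dd)
    }
    D <- D / ncol(v)
    cls[[nm]] <- average_linkage_cluster(D, cutoff = 60)
  }
  cooc <- loop_cooccurrence(cls)
  pairs <- cooc$pairs
  dec <- pairs$loop_a == "CDR_H2" | pairs$loop_b == "CDR_H2"
  expect_gt(min(pairs$cramers_v[!dec]), max(pairs$cramers_v[dec]))
})
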