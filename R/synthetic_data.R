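## Synthetic-data generators with known ground truth. They emulate the two
## ingredients the analysis consumes -- metastable loop-torsion dynamics and
## rigid-body antibody geometry -- so every pipeline stage has a recovery
## test against a known answer, without any MD input.

#' von Mises random angles
#'
#' Best-Fisher rejection sampler for the circular normal distribution.
#' `kappa = 0` falls back to the uniform circle. A 20-degree standard
#' deviation corresponds to `kappa ~ 1 / (20 * pi / 180)^2 ~ 8.2`.
#'
#' @param n sample count.
#' @param mu mean direction in degrees (scalar or length-n vector).
#' @param kappa concentration (>= 0).
#' @return angles in degrees, (-180, 180].
#' @export
rvonmises <- function(n, mu = 0, kappa = 8.2) {
  if (kappa < 0) stopf("kappa must be non-negative")
  if (kappa < 1e-8) return(wrap_angle(stats::runif(n, -180, 180) + mu))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    acc <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    th <- sign(u3[acc] - 0.5) * acos(pmin(pmax(f[acc], -1), 1))
    k <- min(length(th), m)
    if (k > 0L) out[(got + 1L):(got + k)] <- th[seq_len(k)]
    got <- got + k
  }
  wrap_angle(rad2deg(out) + mu)
}

#' Sample a discrete Markov chain
#'
#' @param T row-stochastic transition matrix.
#' @param n length of the path.
#' @param init initial distribution (default: stationary).
#' @return integer path (1..m).
#' @export
sample_markov_chain <- function(T, n, init = NULL) {
  if (any(abs(rowSums(T) - 1) > 1e-8) || any(T < 0))
    stopf("transition matrix must be row-stochastic")
  m <- nrow(T)
  cum <- t(apply(T, 1L, cumsum))
  p0 <- init %||% stationary_distribution(T)
  path <- integer(n)
  path[1L] <- sample.int(m, 1L, prob = p0)
  u <- stats::runif(n)
  for (t in 2L:n) {
    path[t] <- findInterval(u[t], cum[path[t - 1L], ]) + 1L
    if (path[t] > m) path[t] <- m
  }
  path
}

#' Specification for hidden-Markov torsion trajectories
#'
#' Describes metastable CDR-loop torsion dynamics: a hidden Markov chain
#' over conformational macrostates and per-state von Mises torsion
#' emissions per loop. Loops flagged `coupled = TRUE` share one hidden
#' chain (correlated loops); decoupled loops switch on independent chains
#' drawn from the same transition matrix.
#'
#' @param T_true hidden row-stochastic transition matrix (m x m), one step
#'   per frame.
#' @param loops named list; each entry
#'   `list(means = m x d matrix (degrees), kappa =, coupled = TRUE)`.
#' @param n_frames frames to simulate.
#' @param frame_spacing ns per frame (default 0.1).
#' @param seed RNG seed.
#' @return `"hmm_torsion_spec"` list.
#' @export
hmm_torsion_spec <- function(T_true, loops, n_frames,
                             frame_spacing = 0.1, seed = 1L) {
  if (any(abs(rowSums(T_true) - 1) > 1e-8) || any(T_true < 0))
    stopf("T_true must be row-stochastic")
  for (nm in names(loops)) {
    lp <- loops[[nm]]
    if (nrow(lp$means) != nrow(T_true))
      stopf("loop '%s': means must have one row per hidden state", nm)
    if (any(lp$kappa <= 0)) stopf("loop '%s': concentrations must be > 0", nm)
  }
  structure(list(T_true = T_true, loops = loops, n_frames = n_frames,
                 frame_spacing = frame_spacing, seed = seed),
            class = "hmm_torsion_spec")
}

#' Simulate hidden-Markov loop torsions
#'
#' @param spec an [hmm_torsion_spec()].
#' @return list with `torsions` (named list of [new_torsion_series()], one
#'   per loop), `hidden` (master chain path), `hidden_by_loop` (per-loop
#'   path actually used), and `spec`.
#' @export
simulate_hmm_torsions <- function(spec) {
  stopifnot(inherits(spec, "hmm_torsion_spec"))
  set.seed(spec$seed)
  n <- spec$n_frames
  master <- sample_markov_chain(spec$T_true, n)
  torsions <- list()
  hidden_by_loop <- list()
  for (nm in names(spec$loops)) {
    lp <- spec$loops[[nm]]
    coupled <- lp$coupled %||% TRUE
    path <- if (coupled) master else sample_markov_chain(spec$T_true, n)
    hidden_by_loop[[nm]] <- path
    d <- ncol(lp$means)
    kap <- rep(lp$kappa, length.out = d)
    vals <- matrix(NA_real_, n, d)
    for (j in seq_len(d))
      vals[, j] <- rvonmises(n, mu = lp$means[path, j], kappa = kap[j])
    labs <- data.frame(res_id = paste0(nm, ":", seq_len(d)),
                       angle = rep(c("psi", "phi"), length.out = d),
                       stringsAsFactors = FALSE)
    torsions[[nm]] <- new_torsion_series(vals, labs)
  }
  list(torsions = torsions, hidden = master,
       hidden_by_loop = hidden_by_loop, spec = spec)
}

#' Default synthetic paratope fixture
#'
#' The package's reference study condition: six CDR loops, four hidden
#' paratope macrostates with metastable kinetics (stay probabilities about
#' 0.99 per 0.1 ns frame, i.e. slow switching relative to the frame
#' spacing), two torsions per loop, von Mises emissions of about 20-degree
#' width so neighbouring states overlap mildly. Five loops share the hidden
#' chain; CDR-H2 switches independently (the decoupled loop).
#'
#' @param n_frames frames (default 50000).
#' @param seed RNG seed.
#' @param frame_spacing ns per frame (default 0.1).
#' @return an [hmm_torsion_spec()].
#' @export
default_hmm_fixture <- function(n_frames = 50000L, seed = 42L,
                                frame_spacing = 0.1) {
  T_true <- matrix(c(
    0.990, 0.006, 0.002, 0.002,
    0.004, 0.990, 0.004, 0.002,
    0.002, 0.005, 0.990, 0.003,
    0.002, 0.002, 0.004, 0.992), 4L, 4L, byrow = TRUE)
  base1 <- c(-140, -70, 60, 150)
  base2 <- c(120, -45, -160, 30)
  loops <- list()
  loop_names <- c("CDR_L1", "CDR_L2", "CDR_L3", "CDR_H1", "CDR_H2", "CDR_H3")
  for (i in seq_along(loop_names)) {
    loops[[loop_names[i]]] <- list(
      means = cbind(wrap_angle(base1 + 7 * (i - 1)),
                    wrap_angle(base2 - 9 * (i - 1))),
      kappa = 8.2,
      coupled = loop_names[i] != "CDR_H2")
  }
  hmm_torsion_spec(T_true, loops, n_frames = n_frames,
                   frame_spacing = frame_spacing, seed = seed)
}

random_cloud <- function(n, scale) {
  matrix(stats::rnorm(n * 3L, sd = scale), n, 3L)
}

## Translate a cloud so its (uniform-mass) COM sits at `at`.
place_at <- function(cloud, at) sweep(cloud, 2L, colMeans(cloud) - at, `-`)

#' Specification for rigid-body antibody mock trajectories
#'
#' Point-cloud templates per antibody region, rigidly placed every frame so
#' the four interface centers of mass realize a prescribed interface-angle
#' series exactly (before noise), plus optionally switch/constant regions
#' realizing a prescribed elbow-angle series.
#'
#' @param interface_series interface angle (degrees) per frame.
#' @param elbow_series optional elbow angle per frame (adds Fab regions).
#' @param noise_sd isotropic Gaussian coordinate noise in Angstrom.
#' @param atoms_per_region atoms in each template cloud.
#' @param seed RNG seed (templates and noise).
#' @return `"rigid_antibody_spec"` list.
#' @export
rigid_antibody_spec <- function(interface_series, elbow_series = NULL,
                                noise_sd = 0, atoms_per_region = 12L,
                                seed = 1L) {
  if (!is.null(elbow_series) &&
      length(elbow_series) != length(interface_series))
    stopf("elbow series must match interface series length")
  structure(list(interface_series = as.numeric(interface_series),
                 elbow_series = elbow_series, noise_sd = noise_sd,
                 atoms_per_region = as.integer(atoms_per_region),
                 seed = seed),
            class = "rigid_antibody_spec")
}

#' Simulate a rigid-body mock antibody trajectory
#'
#' Builds a Fv (or Fab, when an elbow series is given) from small rigid
#' point-cloud templates: per frame, the light-chain CDR union, VL, VH and
#' heavy-chain CDR union centers of mass are placed on the exact
#' four-point geometry whose torsion equals the prescribed interface
#' angle; switch and constant regions are placed analogously for the elbow
#' angle. Isotropic Gaussian noise is added afterwards. The matching
#' region annotation is returned alongside, so the recovered
#' [interface_angle()] / [elbow_angle()] series can be compared directly
#' with the prescription.
#'
#' @param spec a [rigid_antibody_spec()].
#' @return list with `traj` ([new_trajectory()]), `regions`
#'   ([annotate_regions()]) and `spec`.
#' @export
simulate_rigid_antibody <- function(spec) {
  stopifnot(inherits(spec, "rigid_antibody_spec"))
  set.seed(spec$seed)
  nfr <- length(spec$interface_series)
  na <- spec$atoms_per_region
  r_cdr <- 10; d_vv <- 15     # COM layout scale (Angstrom)
  ## templates (zero-centered clouds), one per region
  tmpl <- list(
    CDR_L1 = random_cloud(na, 1.2), CDR_L2 = random_cloud(na, 1.2),
    CDR_L3 = random_cloud(na, 1.2), FW_L = random_cloud(2L * na, 2.0),
    CDR_H1 = random_cloud(na, 1.2), CDR_H2 = random_cloud(na, 1.2),
    CDR_H3 = random_cloud(na, 1.2), FW_H = random_cloud(2L * na, 2.0))
  fab <- !is.null(spec$elbow_series)
  if (fab) {
    tmpl$SW_L <- random_cloud(na, 1.0)
    tmpl$SW_H <- random_cloud(na, 1.0)
    tmpl$CONST_L <- random_cloud(2L * na, 2.0)
    tmpl$CONST_H <- random_cloud(2L * na, 2.0)
  }
  counts <- vapply(tmpl, nrow, integer(1))
  offsets <- cumsum(c(0L, counts[-length(counts)]))
  names(offsets) <- names(tmpl)
  nat <- sum(counts)
  ## residue layout: one residue per atom, contiguous blocks per region
  chain_of_region <- function(nm) if (grepl("_L", nm) || nm == "FW_L") "L" else "H"
  chains <- character(nat); resno <- integer(nat)
  nextres <- c(L = 0L, H = 0L)
  region_res <- list()
  for (nm in names(tmpl)) {
    ch <- chain_of_region(nm)
    rr <- nextres[ch] + seq_len(counts[nm])
    nextres[ch] <- nextres[ch] + counts[nm]
    idx <- offsets[nm] + seq_len(counts[nm])
    chains[idx] <- ch
    resno[idx] <- rr
    region_res[[nm]] <- range(rr)
  }
  top <- new_topology(data.frame(
    eleno = seq_len(nat), elety = "CA", resid = "ALA", chain = chains,
    resno = resno, insert = "", element = "C", mass = 12.011,
    stringsAsFactors = FALSE))
  cfg <- list(
    VL = list(chain = "L", ranges = list(c(1, region_res$FW_L[2L]))),
    VH = list(chain = "H", ranges = list(c(1, region_res$FW_H[2L]))),
    CDR_L1 = list(chain = "L", ranges = list(region_res$CDR_L1)),
    CDR_L2 = list(chain = "L", ranges = list(region_res$CDR_L2)),
    CDR_L3 = list(chain = "L", ranges = list(region_res$CDR_L3)),
    CDR_H1 = list(chain = "H", ranges = list(region_res$CDR_H1)),
    CDR_H2 = list(chain = "H", ranges = list(region_res$CDR_H2)),
    CDR_H3 = list(chain = "H", ranges = list(region_res$CDR_H3)))
  if (fab) {
    cfg$switch_L <- list(chain = "L", ranges = list(region_res$SW_L))
    cfg$switch_H <- list(chain = "H", ranges = list(region_res$SW_H))
    cfg$CL <- list(chain = "L", ranges = list(region_res$CONST_L))
    cfg$CH1 <- list(chain = "H", ranges = list(region_res$CONST_H))
  }
  ## fixed COM targets
  c_vl <- c(0, 0, 0); c_vh <- c(0, 0, d_vv)
  c_cdrl <- c(r_cdr, 0, 0)
  cdrl_cloud <- place_at(rbind(tmpl$CDR_L1, tmpl$CDR_L2, tmpl$CDR_L3), c_cdrl)
  nC <- nrow(cdrl_cloud)
  nF <- nrow(tmpl$FW_L)
  fwl_cloud <- place_at(tmpl$FW_L, ((nC + nF) * c_vl - nC * c_cdrl) / nF)
  coords <- array(NA_real_, dim = c(nfr, nat, 3L))
  put <- function(f, nm, cloud) {
    idx <- offsets[nm] + seq_len(counts[nm])
    coords[f, idx, ] <<- cloud
  }
  cdrh_tmpl <- rbind(tmpl$CDR_H1, tmpl$CDR_H2, tmpl$CDR_H3)
  if (fab) {
    ## switch axis deliberately offset from the VL-VH axis so the variable
    ## COM never sits on it (a collinear elbow torsion would be degenerate)
    s_h <- c(6, 0, 40); s_l <- c(6, 0, 55)
    swh_cloud <- place_at(tmpl$SW_H, s_h)
    swl_cloud <- place_at(tmpl$SW_L, s_l)
    const_tmpl <- rbind(tmpl$CONST_L, tmpl$CONST_H)
    axis_u <- (s_l - s_h) / sqrt(sum((s_l - s_h)^2))
  }
  for (f in seq_len(nfr)) {
    theta <- spec$interface_series[f]
    phi <- deg2rad(-theta)
    c_cdrh <- c(r_cdr * cos(phi), r_cdr * sin(phi), d_vv)
    cdrh_cloud <- place_at(cdrh_tmpl, c_cdrh)
    fwh_cloud <- place_at(tmpl$FW_H, ((nC + nF) * c_vh - nC * c_cdrh) / nF)
    k <- counts["CDR_L1"]
    put(f, "CDR_L1", cdrl_cloud[seq_len(k), ])
    put(f, "CDR_L2", cdrl_cloud[k + seq_len(k), ])
    put(f, "CDR_L3", cdrl_cloud[2L * k + seq_len(k), ])
    put(f, "FW_L", fwl_cloud)
    put(f, "CDR_H1", cdrh_cloud[seq_len(k), ])
    put(f, "CDR_H2", cdrh_cloud[k + seq_len(k), ])
    put(f, "CDR_H3", cdrh_cloud[2L * k + seq_len(k), ])
    put(f, "FW_H", fwh_cloud)
    if (fab) {
      vframe <- rbind(cdrl_cloud, fwl_cloud, cdrh_cloud, fwh_cloud)
      v <- colMeans(vframe)
      ## basis perpendicular to the switch axis, e1 toward the variable COM
      a1 <- (v - s_h) - sum((v - s_h) * axis_u) * axis_u
      e1 <- a1 / sqrt(sum(a1^2))
      e2 <- cross3(axis_u, e1)
      alpha <- -deg2rad(spec$elbow_series[f])
      c_const <- s_l + 12 * axis_u + 10 * (cos(alpha) * e1 + sin(alpha) * e2)
      const_cloud <- place_at(const_tmpl, c_const)
      put(f, "SW_H", swh_cloud)
      put(f, "SW_L", swl_cloud)
      kc <- counts["CONST_L"]
      put(f, "CONST_L", const_cloud[seq_len(kc), ])
      put(f, "CONST_H", const_cloud[kc + seq_len(kc), ])
    }
  }
  if (spec$noise_sd > 0)
    coords <- coords + array(stats::rnorm(length(coords), sd = spec$noise_sd),
                             dim = dim(coords))
  traj <- new_trajectory(top, coords)
  regions <- annotate_regions(top, cfg, scheme = "synthetic")
  list(traj = traj, regions = regions, spec = spec)
}

#' Metropolis sampling of a quartic double well
#'
#' Samples the Boltzmann distribution of
#' `U(x, y) = barrier * (x^2 - 1)^2 + 2 kT y^2` (kcal/mol): two wells at
#' x = -1 and x = +1 separated by a saddle of height `barrier` at x = 0.
#' x is sampled by a Metropolis random walk, y (independent, harmonic)
#' exactly. The analytic barrier is the ground truth for free-energy
#' surface recovery. A zero barrier degenerates to a single harmonic well
#' `U(x) = kT x^2 / 2`.
#'
#' @param barrier barrier height in kcal/mol (> 0 for two wells).
#' @param kT thermal energy in kcal/mol (default 300 K: 0.596).
#' @param n_steps samples.
#' @param seed RNG seed.
#' @param step_sd Metropolis proposal standard deviation.
#' @param x0 starting point.
#' @return list with `samples` (n x 2 matrix), `barrier`, `kT`,
#'   `acceptance`.
#' @export
simulate_double_well <- function(barrier, kT = 0.0019872041 * 300,
                                 n_steps = 1e5L, seed = 1L,
                                 step_sd = 0.35, x0 = -1) {
  if (barrier < 0) stopf("barrier must be non-negative")
  set.seed(seed)
  ## zero barrier degenerates to a single harmonic well (a flat quartic
  ## would leave the walk unconfined)
  U <- if (barrier > 0) function(x) barrier * (x^2 - 1)^2
       else function(x) kT * x^2 / 2
  prop <- stats::rnorm(n_steps, sd = step_sd)
  luni <- log(stats::runif(n_steps))
  x <- numeric(n_steps)
  cur <- x0
  ucur <- U(cur)
  acc <- 0L
  for (t in seq_len(n_steps)) {
    cand <- cur + prop[t]
    ucand <- U(cand)
    if (luni[t] < (ucur - ucand) / kT) {
      cur <- cand; ucur <- ucand; acc <- acc + 1L
    }
    x[t] <- cur
  }
  y <- stats::rnorm(n_steps, sd = 0.5)   # Boltzmann-exact for U_y = 2 kT y^2
  list(samples = cbind(x = x, y = y), barrier = barrier, kT = kT,
       acceptance = acc / n_steps)
}
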