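# Fixtures built in code: toy PDB text, an internal-coordinate backbone
# builder, and brute-force oracles used as independent references.

# ---- toy PDB text ----------------------------------------------------------

pdb_atom_line <- function(eleno, elety, resid, chain, resno, x, y, z,
                          occ = 1, alt = " ", element = NULL) {
  element <- element %||% substr(trimws(elety), 1, 1)
  sprintf("ATOM  %5d %-4s%s%-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          eleno, formatC(elety, width = 4), alt, resid, chain, resno,
          x, y, z, occ, 0, element)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

toy_pdb_text <- function(coords, elety = "CA", chain = "A",
                         resno = seq_len(nrow(coords)), resid = "ALA") {
  vapply(seq_len(nrow(coords)), function(i)
    pdb_atom_line(i, elety, resid, chain, resno[i],
                  coords[i, 1], coords[i, 2], coords[i, 3]),
    character(1))
}

# ---- internal-coordinate backbone builder (NeRF) ---------------------------

# Place point D given A, B, C and internal coordinates: bond |CD|, angle
# B-C-D (degrees), torsion A-B-C-D (degrees).
nerf_place <- function(A, B, C, bond, angle, torsion) {
  th <- angle * pi / 180
  ph <- -torsion * pi / 180   # sign matches the IUPAC torsion convention
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-bond * cos(th), bond * sin(th) * cos(ph), bond * sin(th) * sin(ph))
  C + d2[1] * bc + d2[2] * m + d2[3] * n
}

# Build an n-residue backbone (N, CA, C per residue) with the given phi/psi
# (recycled); omega fixed at 180. Returns a trajectory with one frame.
build_backbone <- function(n_res, phi = -57, psi = -47, chain = "A") {
  phi <- rep(phi, length.out = n_res)
  psi <- rep(psi, length.out = n_res)
  b_nca <- 1.458; b_cac <- 1.525; b_cn <- 1.329
  a_ncac <- 111.0; a_cacn <- 116.6; a_cnca <- 121.9
  xyz <- matrix(NA_real_, 3 * n_res, 3)
  xyz[1, ] <- c(0, 0, 0)
  xyz[2, ] <- c(b_nca, 0, 0)
  xyz[3, ] <- nerf_place(c(-1, 1, 0), xyz[1, ], xyz[2, ], b_cac, a_ncac, 0)
  for (i in 2:n_res) {
    k <- 3 * (i - 1)
    xyz[k + 1, ] <- nerf_place(xyz[k - 2, ], xyz[k - 1, ], xyz[k, ],
                               b_cn, a_cacn, psi[i - 1])      # N(i): psi(i-1)
    xyz[k + 2, ] <- nerf_place(xyz[k - 1, ], xyz[k, ], xyz[k + 1, ],
                               b_nca, a_cnca, 180)            # CA(i): omega
    xyz[k + 3, ] <- nerf_place(xyz[k, ], xyz[k + 1, ], xyz[k + 2, ],
                               b_cac, a_ncac, phi[i])         # C(i): phi(i)
  }
  top <- new_topology(data.frame(
    eleno = seq_len(3 * n_res),
    elety = rep(c("N", "CA", "C"), n_res),
    resid = "ALA", chain = chain,
    resno = rep(seq_len(n_res), each = 3), insert = "",
    element = rep(c("N", "C", "C"), n_res),
    mass = rep(c(14.007, 12.011, 12.011), n_res),
    stringsAsFactors = FALSE))
  new_trajectory(top, xyz)
}

random_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

transform_trajectory <- function(traj, R = diag(3), t = c(0, 0, 0)) {
  out <- traj
  for (f in seq_len(dim(traj$coords)[1])) {
    out$coords[f, , ] <- sweep(traj$coords[f, , ] %*% R, 2, t, `+`)
  }
  out
}

# ---- brute-force oracles ---------------------------------------------------

# Greedy UPGMA agglomeration, O(n^3), merging the minimum mean inter-cluster
# distance until it exceeds the cutoff.
bf_average_linkage <- function(D, cutoff) {
  clusters <- as.list(seq_len(nrow(D)))
  repeat {
    if (length(clusters) == 1) break
    bestd <- Inf; bi <- bj <- NA
    for (i in seq_len(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        d <- mean(D[clusters[[i]], clusters[[j]]])
        if (d < bestd - 1e-12) { bestd <- d; bi <- i; bj <- j }
      }
    }
    if (bestd > cutoff) break
    clusters[[bi]] <- sort(c(clusters[[bi]], clusters[[bj]]))
    clusters[[bj]] <- NULL
  }
  labels <- integer(nrow(D))
  for (k in seq_along(clusters)) labels[clusters[[k]]] <- k
  labels
}

# Partition agreement irrespective of label names.
same_partition <- function(a, b) {
  identical(outer(a, a, `==`), outer(b, b, `==`))
}

bf_cramers_v <- function(a, b) {
  ua <- sort(unique(a)); ub <- sort(unique(b))
  O <- matrix(0, length(ua), length(ub))
  for (i in seq_along(a)) {
    O[match(a[i], ua), match(b[i], ub)] <- O[match(a[i], ua), match(b[i], ub)] + 1
  }
  n <- sum(O)
  E <- outer(rowSums(O), colSums(O)) / n
  chi2 <- sum((O - E)^2 / E)
  sqrt(chi2 / (n * (min(dim(O)) - 1)))
}

# Empirical mean first-passage time a -> b from a simulated path.
empirical_mfpt <- function(path, a, b) {
  hit_b <- which(path %in% b)
  in_a <- which(path %in% a)
  nxt <- findInterval(in_a, hit_b) + 1
  ok <- nxt <= length(hit_b)
  mean(hit_b[nxt[ok]] - in_a[ok])
}

# Analytic slowest timescale of a transition matrix (per chain step).
true_t2 <- function(T) {
  ev <- sort(Re(eigen(T)$values), decreasing = TRUE)
  -1 / log(ev[2])
}
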