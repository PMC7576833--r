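#' Center of mass of a set of atoms
#'
#' @param coords `n x 3` matrix (Angstrom).
#' @param masses atomic masses (amu); ignored when `mass_weighted = FALSE`.
#' @param mass_weighted if `FALSE`, the unweighted geometric mean is returned.
#' @return length-3 numeric vector.
#' @export
center_of_mass <- function(coords, masses = NULL, mass_weighted = TRUE) {
  if (is.null(dim(coords))) coords <- matrix(coords, ncol = 3L)
  if (nrow(coords) == 0L) stopf("center_of_mass: empty atom selection")
  if (!mass_weighted || is.null(masses)) return(colMeans(coords))
  if (length(masses) != nrow(coords))
    stopf("masses length (%d) does not match atom count (%d)",
          length(masses), nrow(coords))
  colSums(coords * masses) / sum(masses)
}

#' Signed dihedral (torsion) angle between four points
#'
#' IUPAC convention: the cis (eclipsed) arrangement is 0 degrees and the
#' angle is the rotation of the p3-p4 bond relative to p1-p2 viewed along
#' p2-p3. Sign reference case: `(1,0,0), (0,0,0), (0,0,1), (0,1,1)` gives
#' -90 degrees. Inputs may be length-3 vectors (scalar result) or `n x 3`
#' matrices (vectorized over rows).
#'
#' @param p1,p2,p3,p4 points or row-matrices of points.
#' @return angle(s) in degrees, in (-180, 180].
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  asmat <- function(p) if (is.null(dim(p))) matrix(p, ncol = 3L) else p
  p1 <- asmat(p1); p2 <- asmat(p2); p3 <- asmat(p3); p4 <- asmat(p4)
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3m(b1, b2)
  n2 <- cross3m(b2, b3)
  nb2 <- rownorm(b2)
  if (any(nb2 < 1e-10)) stopf("degenerate dihedral: coincident central points")
  if (any(rownorm(n1) < 1e-10) || any(rownorm(n2) < 1e-10))
    stopf("degenerate dihedral: collinear bond triplet")
  u2 <- b2 / nb2
  m1 <- cross3m(n1, u2)
  x <- rowSums(n1 * n2)
  y <- rowSums(m1 * n2)
  wrap_angle(rad2deg(atan2(y, x)))
}

region_com_series <- function(traj, residues, elety = NULL,
                              mass_weighted = TRUE, heavy_only = TRUE) {
  idx <- select_atoms(traj$topology, residues = residues, elety = elety,
                      heavy_only = heavy_only)
  if (length(idx) == 0L) stopf("region selects no atoms")
  m <- traj$topology$atoms$mass[idx]
  nfr <- n_frames(traj)
  out <- matrix(NA_real_, nfr, 3L)
  for (k in 1:3) {
    sub <- traj$coords[, idx, k, drop = FALSE]
    dim(sub) <- c(nfr, length(idx))
    out[, k] <- if (mass_weighted) (sub %*% m) / sum(m) else rowMeans(sub)
  }
  out
}

#' VH-VL interface angle series
#'
#' The relative orientation of the two variable domains is measured as a
#' signed torsion over four centers of mass: COM of the light-chain CDR
#' loops, COM of the VL domain, COM of the VH domain, and COM of the
#' heavy-chain CDR loops. "CDR loops of a chain" is the union of its three
#' CDR sets (DE loops excluded by default).
#'
#' @param traj a [new_trajectory()].
#' @param regions an [annotate_regions()] object with `VL`, `VH` and the six
#'   CDR sets.
#' @param mass_weighted use mass-weighted COMs (default) or geometric means.
#' @param elety optional atom-name filter (e.g. `"CA"`); default all heavy
#'   atoms.
#' @param include_de include the DE loops (`L4`/`H4`) in the CDR unions.
#' @return Object of class `"angle_series"`: numeric vector (degrees,
#'   per frame) with a `definition` attribute recording the four COMs used.
#' @export
interface_angle <- function(traj, regions, mass_weighted = TRUE,
                            elety = NULL, include_de = FALSE) {
  need <- c("VL", "VH", "CDR_L1", "CDR_L2", "CDR_L3",
            "CDR_H1", "CDR_H2", "CDR_H3")
  miss <- setdiff(need, names(regions))
  if (length(miss)) stopf("interface_angle: missing region(s): %s",
                          paste(miss, collapse = ", "))
  cdrs_l <- unique(unlist(regions[c("CDR_L1", "CDR_L2", "CDR_L3",
                                    if (include_de) "L4")], use.names = FALSE))
  cdrs_h <- unique(unlist(regions[c("CDR_H1", "CDR_H2", "CDR_H3",
                                    if (include_de) "H4")], use.names = FALSE))
  p1 <- region_com_series(traj, cdrs_l, elety, mass_weighted)
  p2 <- region_com_series(traj, regions$VL, elety, mass_weighted)
  p3 <- region_com_series(traj, regions$VH, elety, mass_weighted)
  p4 <- region_com_series(traj, cdrs_h, elety, mass_weighted)
  ang <- dihedral_angle(p1, p2, p3, p4)
  structure(ang, class = "angle_series",
            definition = list(points = c("COM(CDRs_L)", "COM(VL)", "COM(VH)",
                                         "COM(CDRs_H)"),
                              mass_weighted = mass_weighted, elety = elety))
}

#' Fab elbow angle series
#'
#' The hinge between the variable and constant modules of a Fab, measured as
#' a torsion over (COM of the variable module VH+VL, COM of the heavy-chain
#' switch region, COM of the light-chain switch region, COM of the constant
#' module CH1+CL); the two switch-region COMs realize the central axis
#' connecting the modules.
#'
#' @inheritParams interface_angle
#' @return An `"angle_series"` (degrees per frame).
#' @export
elbow_angle <- function(traj, regions, mass_weighted = TRUE, elety = NULL) {
  need <- c("VL", "VH", "CL", "CH1", "switch_L", "switch_H")
  miss <- setdiff(need, names(regions))
  if (length(miss))
    stopf("elbow angle requires constant domains and switch regions (missing: %s)",
          paste(miss, collapse = ", "))
  vres <- unique(c(regions$VL, regions$VH))
  cres <- unique(c(regions$CL, regions$CH1))
  p1 <- region_com_series(traj, vres, elety, mass_weighted)
  p2 <- region_com_series(traj, regions$switch_H, elety, mass_weighted)
  p3 <- region_com_series(traj, regions$switch_L, elety, mass_weighted)
  p4 <- region_com_series(traj, cres, elety, mass_weighted)
  ang <- dihedral_angle(p1, p2, p3, p4)
  structure(ang, class = "angle_series",
            definition = list(points = c("COM(V)", "COM(switch_H)",
                                         "COM(switch_L)", "COM(C)"),
                              mass_weighted = mass_weighted, elety = elety))
}

#' Least-squares rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation (det = +1) and translation minimizing the RMSD
#' between corresponding fit atoms. The fitted mobile coordinates are
#' `sweep(mobile, 2, cm_mob) %*% rotation + cm_ref` applied to all atoms.
#'
#' @param mobile,reference `n x 3` coordinate matrices.
#' @param fit row indices used for the fit (default: all; at least 3
#'   non-collinear points required).
#' @return list with `rotation` (3x3), `cm_mobile`, `cm_reference`,
#'   `rmsd` (over the fit atoms) and `fitted` (all mobile atoms,
#'   transformed).
#' @export
superpose <- function(mobile, reference, fit = NULL) {
  fit <- fit %||% seq_len(nrow(mobile))
  if (length(fit) < 3L) stopf("superpose needs at least 3 fit atoms")
  P <- mobile[fit, , drop = FALSE]
  Q <- reference[fit, , drop = FALSE]
  if (nrow(P) != nrow(Q)) stopf("fit selections differ in atom count")
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2L, cp); Qc <- sweep(Q, 2L, cq)
  H <- crossprod(Pc, Qc)
  s <- svd(H)
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  fitted_fit <- Pc %*% R
  rmsd <- sqrt(mean(rowSums((fitted_fit - Qc)^2)))
  fitted <- sweep(sweep(mobile, 2L, cp) %*% R, 2L, cq, `+`)
  list(rotation = R, cm_mobile = cp, cm_reference = cq,
       rmsd = rmsd, fitted = fitted)
}

#' RMSD of a region after superposition on another region
#'
#' Superposes frame `a` onto frame `b` using the fit region (by residue-id
#' correspondence), then reports the RMSD over the rmsd region without
#' refitting. The standard use is fitting on the Fv framework and reading
#' the displacement of one CDR loop.
#'
#' @param traj_a,traj_b trajectories (frames selected by `frame_a`/`frame_b`).
#' @param fit_region,rmsd_region residue-id character vectors.
#' @param elety atom-name filter, default `"CA"`.
#' @param frame_a,frame_b frame indices (default 1).
#' @return RMSD in Angstrom.
#' @export
region_rmsd <- function(traj_a, traj_b, fit_region, rmsd_region,
                        elety = "CA", frame_a = 1L, frame_b = 1L) {
  sel_pair <- function(region) {
    ia <- select_atoms(traj_a$topology, residues = region, elety = elety)
    ib <- select_atoms(traj_b$topology, residues = region, elety = elety)
    key_a <- paste0(traj_a$topology$atoms$res_id[ia], "|",
                    trimws(traj_a$topology$atoms$elety[ia]))
    key_b <- paste0(traj_b$topology$atoms$res_id[ib], "|",
                    trimws(traj_b$topology$atoms$elety[ib]))
    common <- intersect(key_a, key_b)
    un <- union(setdiff(key_a, key_b), setdiff(key_b, key_a))
    if (length(un))
      stopf("unmatched residues/atoms between structures: %s",
            paste(utils::head(un, 8L), collapse = ", "))
    list(a = ia[match(common, key_a)], b = ib[match(common, key_b)])
  }
  fsel <- sel_pair(fit_region)
  rsel <- sel_pair(rmsd_region)
  A <- frame_coords(traj_a, frame_a)
  B <- frame_coords(traj_b, frame_b)
  ## fit on fit_region correspondence
  P <- A[fsel$a, , drop = FALSE]
  Q <- B[fsel$b, , drop = FALSE]
  cp <- colMeans(P); cq <- colMeans(Q)
  H <- crossprod(sweep(P, 2, cp), sweep(Q, 2, cq))
  s <- svd(H)
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  Ar <- sweep(sweep(A[rsel$a, , drop = FALSE], 2, cp) %*% R, 2, cq, `+`)
  Br <- B[rsel$b, , drop = FALSE]
  sqrt(mean(rowSums((Ar - Br)^2)))
}
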