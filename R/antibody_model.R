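#' @importFrom bio3d read.pdb write.pdb atom2mass
NULL

#' Construct a topology object
#'
#' A topology records the atoms of a molecular system: atom names, elements,
#' masses (amu), residue numbers with insertion codes, residue names and chain
#' identifiers. Residue identity is the triple (chain, residue number,
#' insertion code), which antibody numbering schemes require.
#'
#' @param atoms data.frame with columns `eleno`, `elety`, `resid`, `chain`,
#'   `resno`, `insert` (may be `NA`), `element`, `mass`.
#' @return An object of class `"topology"`.
#' @export
new_topology <- function(atoms) {
  need <- c("eleno", "elety", "resid", "chain", "resno", "insert",
            "element", "mass")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stopf("topology atoms lack columns: %s",
                          paste(miss, collapse = ", "))
  if (nrow(atoms) == 0L) stopf("topology must contain at least one atom")
  if (any(!is.finite(atoms$mass)) || any(atoms$mass <= 0))
    stopf("all atom masses must be positive")
  atoms$insert[is.na(atoms$insert)] <- ""
  atoms$res_id <- paste0(atoms$chain, ":", atoms$resno, atoms$insert)
  residues <- unique(atoms$res_id)
  structure(list(atoms = atoms, residues = residues), class = "topology")
}

#' @export
print.topology <- function(x, ...) {
  cat(sprintf("topology: %d atoms, %d residues, chains: %s\n",
              nrow(x$atoms), length(x$residues),
              paste(unique(x$atoms$chain), collapse = " ")))
  invisible(x)
}

#' Construct a trajectory object
#'
#' A trajectory couples a topology with a `frames x atoms x 3` coordinate
#' array in Angstrom, and an optional frame spacing (time between saved
#' frames, in ns) used to convert lag times and timescales to physical units.
#'
#' @param topology a [new_topology()] object.
#' @param coords numeric array `frames x atoms x 3` (a single-frame
#'   `atoms x 3` matrix is promoted).
#' @param frame_spacing optional time per saved frame in ns.
#' @return An object of class `"trajectory"`.
#' @export
new_trajectory <- function(topology, coords, frame_spacing = NULL) {
  if (is.matrix(coords)) coords <- array(coords, dim = c(1L, dim(coords)))
  if (length(dim(coords)) != 3L || dim(coords)[3L] != 3L)
    stopf("coords must be a frames x atoms x 3 array")
  if (dim(coords)[2L] != nrow(topology$atoms))
    stopf("coords have %d atoms but topology has %d",
          dim(coords)[2L], nrow(topology$atoms))
  if (dim(coords)[1L] < 1L) stopf("trajectory must contain at least one frame")
  if (any(!is.finite(coords))) stopf("coordinates must be finite")
  structure(list(topology = topology, coords = coords,
                 frame_spacing = frame_spacing), class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d frames, %d atoms%s\n",
              dim(x$coords)[1L], dim(x$coords)[2L],
              if (!is.null(x$frame_spacing))
                sprintf(", %.4g ns/frame", x$frame_spacing) else ""))
  invisible(x)
}

n_frames <- function(traj) dim(traj$coords)[1L]

## One frame as an atoms x 3 matrix.
frame_coords <- function(traj, i) traj$coords[i, , , drop = TRUE]

topology_from_bio3d <- function(pdb) {
  at <- pdb$atom
  elesy <- at$elesy
  if (is.null(elesy) || all(is.na(elesy))) elesy <- substr(trimws(at$elety), 1, 1)
  elesy[is.na(elesy) | elesy == ""] <- substr(trimws(at$elety), 1, 1)[is.na(elesy) | elesy == ""]
  mass <- tryCatch(bio3d::atom2mass(pdb), error = function(e) NULL)
  if (is.null(mass)) {
    lut <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
             P = 30.974, SE = 78.971)
    mass <- lut[toupper(elesy)]
    mass[is.na(mass)] <- 12.011
  }
  new_topology(data.frame(
    eleno = at$eleno, elety = at$elety, resid = at$resid, chain = at$chain,
    resno = at$resno, insert = ifelse(is.na(at$insert), "", at$insert),
    element = toupper(elesy), mass = as.numeric(mass),
    stringsAsFactors = FALSE))
}

#' Read a structure (single- or multi-model PDB) into a trajectory
#'
#' Parses ATOM records of a PDB file; every MODEL becomes one frame.
#' Alternate locations are resolved to the highest-occupancy conformer,
#' ties broken by alphabetically smallest altloc identifier. A duplicated
#' atom (same residue, atom name and altloc) is a parse error.
#'
#' @param pdb a file path, or a character vector of PDB lines.
#' @param frame_spacing optional ns per frame stored on the result.
#' @return A [new_trajectory()] with one frame per MODEL.
#' @export
read_structure <- function(pdb, frame_spacing = NULL) {
  file <- pdb
  if (length(pdb) == 1L && !file.exists(pdb) &&
      (grepl("\\.(pdb|ent)$", pdb, ignore.case = TRUE) || !grepl("\n", pdb) &&
         grepl("/", pdb) || pdb == ""))
    stopf("structure file not found: '%s'", pdb)
  if (length(pdb) > 1L || !file.exists(pdb[1L])) {
    file <- tempfile(fileext = ".pdb")
    writeLines(pdb, file)
    on.exit(unlink(file))
  }
  p <- tryCatch(
    bio3d::read.pdb(file, multi = TRUE, rm.alt = FALSE, verbose = FALSE),
    error = function(e) stopf("PDB parse error: %s", conditionMessage(e)))
  keep <- p$atom$type == "ATOM"
  if (!any(keep)) stopf("no ATOM records found in '%s'", file)
  at <- p$atom
  at$row <- seq_len(nrow(at))
  at <- at[keep, , drop = FALSE]
  alt <- ifelse(is.na(at$alt), "", at$alt)
  occ <- ifelse(is.na(at$o), 1, at$o)
  akey <- paste0(at$chain, ":", at$resno, ifelse(is.na(at$insert), "", at$insert),
                 ":", at$elety)
  full <- paste0(akey, ":", alt)
  if (anyDuplicated(full)) {
    d <- at$row[duplicated(full)][1L]
    stopf("duplicate atom record within residue/altloc at atom serial %s (file row %d)",
          at$eleno[match(full[duplicated(full)][1L], full)], d)
  }
  ## altloc resolution: highest occupancy, then alphabetical altloc
  ord <- order(akey, -occ, alt)
  sel <- ord[!duplicated(akey[ord])]
  sel <- sort(sel)
  at <- at[sel, , drop = FALSE]
  xyz <- p$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  idx <- which(keep)[sel]
  cols <- as.vector(rbind(3L * idx - 2L, 3L * idx - 1L, 3L * idx))
  xyz <- xyz[, cols, drop = FALSE]
  nfr <- nrow(xyz)
  nat <- length(idx)
  coords <- array(NA_real_, dim = c(nfr, nat, 3L))
  for (k in 1:3) coords[, , k] <- xyz[, seq(k, by = 3L, length.out = nat), drop = FALSE]
  psub <- p
  psub$atom <- at
  top <- topology_from_bio3d(psub)
  new_trajectory(top, coords, frame_spacing = frame_spacing)
}

#' Read and concatenate trajectory frames from multiple files
#'
#' Frames are concatenated in file order; each file must be atom-compatible
#' with the supplied topology (same atom count).
#'
#' @param files character vector of (multi-model) PDB paths.
#' @param topology reference [new_topology()].
#' @param frame_spacing optional ns per frame.
#' @return A [new_trajectory()]; attribute `"frames_per_file"` logs per-file
#'   frame counts.
#' @export
read_trajectory <- function(files, topology, frame_spacing = NULL) {
  if (length(files) == 0L) stopf("empty file list")
  nat <- nrow(topology$atoms)
  parts <- vector("list", length(files))
  counts <- integer(length(files))
  for (i in seq_along(files)) {
    tr <- read_structure(files[i])
    if (dim(tr$coords)[2L] != nat)
      stopf("atom-count mismatch in '%s': file has %d atoms, topology has %d",
            files[i], dim(tr$coords)[2L], nat)
    parts[[i]] <- tr$coords
    counts[i] <- dim(tr$coords)[1L]
  }
  coords <- array(NA_real_, dim = c(sum(counts), nat, 3L))
  off <- 0L
  for (i in seq_along(parts)) {
    coords[off + seq_len(counts[i]), , ] <- parts[[i]]
    off <- off + counts[i]
  }
  out <- new_trajectory(topology, coords, frame_spacing = frame_spacing)
  attr(out, "frames_per_file") <- stats::setNames(counts, files)
  out
}

#' Write a trajectory as a (multi-model) PDB file
#'
#' @param traj a [new_trajectory()].
#' @param file output path.
#' @param frames which frames to write (default all).
#' @return `file`, invisibly.
#' @export
write_trajectory_pdb <- function(traj, file, frames = NULL) {
  frames <- frames %||% seq_len(n_frames(traj))
  at <- traj$topology$atoms
  nat <- nrow(at)
  xyz <- matrix(NA_real_, nrow = length(frames), ncol = 3L * nat)
  for (f in seq_along(frames)) {
    xyz[f, ] <- as.vector(t(traj$coords[frames[f], , ]))
  }
  pdb <- list(atom = data.frame(
    type = "ATOM", eleno = at$eleno, elety = at$elety, alt = NA,
    resid = at$resid, chain = at$chain, resno = at$resno,
    insert = ifelse(at$insert == "", NA, at$insert),
    x = xyz[1, seq(1, by = 3, length.out = nat)],
    y = xyz[1, seq(2, by = 3, length.out = nat)],
    z = xyz[1, seq(3, by = 3, length.out = nat)],
    o = 1, b = 0, segid = NA, elesy = at$element, charge = NA,
    stringsAsFactors = FALSE), xyz = xyz[1, , drop = TRUE])
  class(pdb) <- "pdb"
  bio3d::write.pdb(pdb, xyz = xyz, file = file)
  invisible(file)
}

res_ids_for_range <- function(topology, chain, ranges) {
  at <- topology$atoms
  ids <- character(0)
  for (r in ranges) {
    sel <- at$chain == chain & at$resno >= r[1L] & at$resno <= r[2L]
    ids <- c(ids, at$res_id[sel])
  }
  ## unique, in topology order
  unique(ids[order(match(ids, at$res_id))])
}

#' Chothia CDR boundary preset
#'
#' Returns CDR residue ranges under the Chothia definition, to be used with
#' structures numbered in the Kabat/Chothia scheme. Never applied silently:
#' pass the result explicitly into a region config.
#'
#' @param light,heavy chain identifiers of light and heavy chain.
#' @return Named list of region definitions suitable for [annotate_regions()].
#' @export
cdr_preset_chothia <- function(light = "L", heavy = "H") {
  list(
    CDR_L1 = list(chain = light, ranges = list(c(24, 34))),
    CDR_L2 = list(chain = light, ranges = list(c(50, 56))),
    CDR_L3 = list(chain = light, ranges = list(c(89, 97))),
    CDR_H1 = list(chain = heavy, ranges = list(c(26, 32))),
    CDR_H2 = list(chain = heavy, ranges = list(c(52, 56))),
    CDR_H3 = list(chain = heavy, ranges = list(c(95, 102))))
}

#' North CDR boundary preset
#'
#' CDR ranges under the North clustering definition (for structures in
#' Kabat/Chothia numbering). See [cdr_preset_chothia()].
#'
#' @inheritParams cdr_preset_chothia
#' @return Named list of region definitions.
#' @export
cdr_preset_north <- function(light = "L", heavy = "H") {
  list(
    CDR_L1 = list(chain = light, ranges = list(c(24, 34))),
    CDR_L2 = list(chain = light, ranges = list(c(49, 56))),
    CDR_L3 = list(chain = light, ranges = list(c(89, 97))),
    CDR_H1 = list(chain = heavy, ranges = list(c(23, 35))),
    CDR_H2 = list(chain = heavy, ranges = list(c(50, 58))),
    CDR_H3 = list(chain = heavy, ranges = list(c(93, 102))))
}

.domain_of_cdr <- c(CDR_L1 = "VL", CDR_L2 = "VL", CDR_L3 = "VL", L4 = "VL",
                    CDR_H1 = "VH", CDR_H2 = "VH", CDR_H3 = "VH", H4 = "VH")

#' Annotate antibody regions on a topology
#'
#' Resolves a region configuration (chain + residue ranges per region) to
#' explicit residue-id sets and validates them: CDR loops must lie inside
#' their variable domain, CDR sets on one chain must be disjoint, and every
#' requested region must be non-empty. Region names follow the field's
#' nomenclature: `VL`, `VH`, `CL`, `CH1`, `CDR_L1..L3`, `CDR_H1..H3`,
#' optional DE loops `L4`/`H4`, and `switch_L`/`switch_H`.
#'
#' If `CL`/`CH1` are defined but switch regions are not, each switch region
#' defaults to the 4 residues flanking the V/C junction of its chain (last
#' two of the variable set, first two of the constant set, in topology
#' order).
#'
#' @param topology a [new_topology()].
#' @param config named list: each entry `list(chain =, ranges = list(c(lo, hi), ...))`;
#'   or a YAML file path readable by [read_region_config()].
#' @param scheme numbering-scheme tag stored on the result (e.g. `"sequential"`,
#'   `"chothia"`).
#' @return Object of class `"antibody_regions"`: named list of residue-id
#'   character vectors with attributes `scheme`.
#' @export
annotate_regions <- function(topology, config, scheme = "sequential") {
  if (is.character(config) && length(config) == 1L)
    config <- read_region_config(config)
  if (!is.null(config$scheme)) {
    scheme <- config$scheme
    config$scheme <- NULL
  }
  sets <- list()
  for (nm in names(config)) {
    cf <- config[[nm]]
    ranges <- cf$ranges
    if (is.numeric(ranges)) ranges <- list(ranges)
    ids <- res_ids_for_range(topology, cf$chain, ranges)
    if (length(ids) == 0L)
      stopf("region '%s' has no residues (chain %s, ranges %s absent from topology)",
            nm, cf$chain, paste(vapply(ranges, function(r)
              paste(r, collapse = "-"), ""), collapse = ","))
    sets[[nm]] <- ids
  }
  ## switch-region defaults from the V/C junction
  for (ch in c("L", "H")) {
    sw <- paste0("switch_", ch)
    vd <- if (ch == "L") "VL" else "VH"
    cd <- if (ch == "L") "CL" else "CH1"
    if (is.null(sets[[sw]]) && !is.null(sets[[vd]]) && !is.null(sets[[cd]])) {
      v <- sets[[vd]]; k <- sets[[cd]]
      sets[[sw]] <- c(utils::tail(v, 2L), utils::head(k, 2L))
    }
  }
  ## validation
  for (nm in names(sets)) {
    dom <- .domain_of_cdr[nm]
    if (!is.na(dom) && !is.null(sets[[dom]])) {
      out <- setdiff(sets[[nm]], sets[[dom]])
      if (length(out))
        stopf("CDR region '%s' is not contained in its domain '%s' (outside: %s)",
              nm, dom, paste(utils::head(out, 5L), collapse = ", "))
    }
  }
  cdr_names <- intersect(names(sets), names(.domain_of_cdr))
  for (ch in c("L", "H")) {
    cdrs <- cdr_names[grepl(paste0("(^CDR_", ch, ")|(^", ch, "4$)"), cdr_names)]
    if (length(cdrs) > 1L) {
      all_ids <- unlist(sets[cdrs], use.names = FALSE)
      if (anyDuplicated(all_ids))
        stopf("CDR regions on chain %s overlap: residue %s in more than one loop",
              ch, all_ids[duplicated(all_ids)][1L])
    }
  }
  structure(sets, class = "antibody_regions", scheme = scheme)
}

#' @export
print.antibody_regions <- function(x, ...) {
  cat(sprintf("antibody regions (%s numbering):\n", attr(x, "scheme")))
  for (nm in names(x)) cat(sprintf("  %-10s %4d residues\n", nm, length(x[[nm]])))
  invisible(x)
}

#' Read a region configuration from a YAML file
#'
#' Expected layout: a top-level `scheme` tag and a `regions` mapping,
#' each region `{chain: L, ranges: [[24, 34]]}`.
#'
#' @param path YAML file.
#' @return Named list usable as `config` in [annotate_regions()].
#' @export
read_region_config <- function(path) {
  y <- yaml::read_yaml(path)
  regions <- y$regions %||% y
  out <- list()
  for (nm in names(regions)) {
    if (nm == "scheme") next
    cf <- regions[[nm]]
    rg <- cf$ranges
    if (is.numeric(rg)) rg <- list(rg)
    rg <- lapply(rg, function(r) as.numeric(unlist(r)))
    out[[nm]] <- list(chain = as.character(cf$chain), ranges = rg)
  }
  out$scheme <- y$scheme %||% "sequential"
  out
}

## Atom index selection by residue ids and optional atom-name filter.
select_atoms <- function(topology, residues = NULL, elety = NULL,
                         heavy_only = FALSE) {
  at <- topology$atoms
  sel <- rep(TRUE, nrow(at))
  if (!is.null(residues)) sel <- sel & at$res_id %in% residues
  if (!is.null(elety)) sel <- sel & trimws(at$elety) %in% elety
  if (heavy_only) sel <- sel & toupper(at$element) != "H"
  which(sel)
}
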