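#' Shrake-Rupley solvent accessible surface area
#'
#' Classic point-counting SASA: each atom is covered with a deterministic
#' golden-spiral point set on a sphere of radius `r_vdw + probe`; the area is
#' the fraction of points not buried inside any neighbour's expanded sphere
#' times `4*pi*(r_vdw + probe)^2`. Hydrogens are excluded by default (the
#' usual convention for crystal structures without placed hydrogens).
#'
#' @param structure A `protein_structure`.
#' @param config An [analysis_config()] (probe radius, point count, radii).
#' @param include_hydrogens Include hydrogen atoms as both surface and
#'   occluders (default FALSE).
#' @param include_het Include HETATM records (default FALSE: protein atoms
#'   only).
#' @return The atom tibble restricted to the atoms used, with an added `asa`
#'   column (Angstrom^2 per atom).
#' @export
shrake_rupley_asa <- function(structure, config = analysis_config(),
                              include_hydrogens = FALSE,
                              include_het = FALSE) {
  at <- structure$atoms
  keep <- (if (include_het) rep(TRUE, nrow(at)) else at$type == "ATOM")
  if (!include_hydrogens) keep <- keep & !at$is_h
  at <- at[keep, ]
  if (nrow(at) == 0) stop_input("no atoms selected for ASA computation")
  unknown <- setdiff(unique(at$element), names(config$vdw_radii))
  if (length(unknown) > 0) {
    stop_input(paste0("no van der Waals radius configured for element(s): ",
                      paste(unknown, collapse = ", ")),
               class = "ssphot_config_error")
  }
  xyz <- atom_xyz(at)
  radii <- unname(config$vdw_radii[at$element]) + config$probe_radius
  pts <- .sphere_points(config$sphere_points)
  n <- nrow(at)
  asa <- numeric(n)
  max_r <- max(radii)
  for (i in seq_len(n)) {
    ri <- radii[i]
    # only spheres overlapping atom i's expanded sphere can bury its points
    dx <- xyz[, 1] - xyz[i, 1]
    dy <- xyz[, 2] - xyz[i, 2]
    dz <- xyz[, 3] - xyz[i, 3]
    d2 <- dx * dx + dy * dy + dz * dz
    nb <- which(d2 < (ri + radii)^2 & seq_len(n) != i)
    if (length(nb) == 0) {
      asa[i] <- 4 * pi * ri^2
      next
    }
    p <- pts * ri
    p1 <- p[, 1] + xyz[i, 1]
    p2 <- p[, 2] + xyz[i, 2]
    p3 <- p[, 3] + xyz[i, 3]
    free <- rep(TRUE, nrow(pts))
    for (j in nb) {
      rj2 <- radii[j]^2
      dj2 <- (p1 - xyz[j, 1])^2 + (p2 - xyz[j, 2])^2 + (p3 - xyz[j, 3])^2
      free <- free & (dj2 > rj2)
      if (!any(free)) break
    }
    asa[i] <- 4 * pi * ri^2 * sum(free) / nrow(pts)
  }
  at$asa <- asa
  at
}

# deterministic golden-spiral (Fibonacci) unit-sphere point set
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Side-chain solvent accessibility of a bonded cysteine pair
#'
#' Sum of the per-atom areas over the CB and SG atoms of each half-cystine,
#' computed in the intact structure (the bond partner and all other atoms act
#' as occluders), plus the percentage of the reference fully-exposed Cys
#' side-chain area.
#'
#' @param structure A `protein_structure`.
#' @param bond A row of [detect_disulfides()] output.
#' @param config An [analysis_config()].
#' @param areas Optional precomputed [shrake_rupley_asa()] table for the full
#'   structure (saves recomputation across bonds).
#' @return One-row tibble: `asa1`, `asa2` (Angstrom^2), `pct1`, `pct2`
#'   (percent of `config$cys_ref_asa`).
#' @export
cys_side_chain_asa <- function(structure, bond, config = analysis_config(),
                               areas = NULL) {
  if (is.null(areas)) areas <- shrake_rupley_asa(structure, config)
  refs <- .bond_refs(bond)
  side <- function(i) {
    sel <- areas$chain_id == refs$chain_id[i] &
      areas$res_seq == refs$res_seq[i] &
      areas$atom_name %in% c("CB", "SG")
    sum(areas$asa[sel])
  }
  a1 <- side(1)
  a2 <- side(2)
  tibble(asa1 = a1, asa2 = a2,
         pct1 = 100 * a1 / config$cys_ref_asa,
         pct2 = 100 * a2 / config$cys_ref_asa)
}
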