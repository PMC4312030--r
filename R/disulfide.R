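#' Analysis configuration
#'
#' Thresholds, radii and discretisation settings shared by the structural
#' analyses. Defaults follow common structural-biology practice: an SG-SG
#' detection window of 1.8-2.5 Angstrom around the ideal 2.05 Angstrom
#' disulphide bond (wide enough for low-resolution coordinates), a van der
#' Waals contact distance of 5.2, "near" and proximity cutoffs of 6 and 8,
#' a 1.4 Angstrom water probe, 960 sphere points for Shrake-Rupley areas and
#' the 104 Angstrom^2 reference side-chain area of an extended Gly-Cys-Gly
#' cysteine.
#'
#' @param sg_detect_window Length-2 numeric, SG-SG distance window (Angstrom).
#' @param vdw_contact Van der Waals contact distance (Angstrom).
#' @param near_threshold "Close proximity" cutoff used for contact tables.
#' @param proximity_threshold Cutoff for counting aromatics near disulphides.
#' @param tyr_cluster_threshold Single-linkage threshold for Tyr clusters.
#' @param probe_radius Solvent probe radius (Angstrom).
#' @param sphere_points Number of test points per atom for Shrake-Rupley.
#' @param cys_ref_asa Reference fully-exposed Cys side-chain area (Angstrom^2).
#' @param vdw_radii Named element -> radius (Angstrom) table.
#' @return A list of class `ssphot_config`.
#' @export
analysis_config <- function(sg_detect_window = c(1.8, 2.5),
                            vdw_contact = 5.2,
                            near_threshold = 6.0,
                            proximity_threshold = 8.0,
                            tyr_cluster_threshold = 6.0,
                            probe_radius = 1.4,
                            sphere_points = 960L,
                            cys_ref_asa = 104,
                            vdw_radii = c(C = 1.70, N = 1.55, O = 1.52,
                                          S = 1.80, H = 1.20, P = 1.80,
                                          SE = 1.90)) {
  stopifnot(length(sg_detect_window) == 2,
            sg_detect_window[1] > 0,
            sg_detect_window[1] < sg_detect_window[2],
            vdw_contact > 0, near_threshold > 0, proximity_threshold > 0,
            tyr_cluster_threshold > 0, probe_radius > 0,
            sphere_points >= 10, cys_ref_asa > 0)
  structure(list(sg_detect_window = sg_detect_window,
                 vdw_contact = vdw_contact,
                 near_threshold = near_threshold,
                 proximity_threshold = proximity_threshold,
                 tyr_cluster_threshold = tyr_cluster_threshold,
                 probe_radius = probe_radius,
                 sphere_points = as.integer(sphere_points),
                 cys_ref_asa = cys_ref_asa,
                 vdw_radii = vdw_radii),
            class = "ssphot_config")
}

#' Detect disulphide bonds
#'
#' Pairs cysteine SG atoms whose separation falls inside the detection window,
#' each SG joining at most one bond (greedy nearest pairing; distance ties
#' resolved by residue order).
#'
#' @param structure A `protein_structure`.
#' @param config An [analysis_config()].
#' @return Tibble with one row per bond: `bond_id` (e.g. `"C737-C765"`),
#'   `cys1_chain`, `cys1_res_seq`, `cys1_icode`, `cys2_chain`, `cys2_res_seq`,
#'   `cys2_icode`, `sg_distance`, sorted by `cys1_res_seq`. Empty tibble when
#'   no cystines are found.
#' @export
detect_disulfides <- function(structure, config = analysis_config()) {
  at <- structure$atoms
  sg <- at[at$type == "ATOM" & at$res_name == "CYS" & at$atom_name == "SG" &
             !at$is_h, ]
  empty <- tibble(bond_id = character(), cys1_chain = character(),
                  cys1_res_seq = integer(), cys1_icode = character(),
                  cys2_chain = character(), cys2_res_seq = integer(),
                  cys2_icode = character(), sg_distance = double())
  if (nrow(sg) < 2) return(empty)
  sg <- arrange(sg, .data$chain_id, .data$res_seq)
  xyz <- atom_xyz(sg)
  d <- as.matrix(stats::dist(xyz))
  cand <- which(upper.tri(d) & d >= config$sg_detect_window[1] &
                  d <= config$sg_detect_window[2], arr.ind = TRUE)
  if (nrow(cand) == 0) return(empty)
  ord <- order(d[cand], cand[, 1], cand[, 2])
  cand <- cand[ord, , drop = FALSE]
  used <- logical(nrow(sg))
  rows <- list()
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]
    if (used[i] || used[j]) next
    used[i] <- used[j] <- TRUE
    rows[[length(rows) + 1]] <- tibble(
      bond_id = paste0("C", sg$res_seq[i], "-C", sg$res_seq[j]),
      cys1_chain = sg$chain_id[i], cys1_res_seq = sg$res_seq[i],
      cys1_icode = sg$icode[i],
      cys2_chain = sg$chain_id[j], cys2_res_seq = sg$res_seq[j],
      cys2_icode = sg$icode[j],
      sg_distance = d[i, j])
  }
  arrange(bind_rows(rows), .data$cys1_res_seq)
}

#' Cystine side-chain dihedrals chi1-chi5
#'
#' The five torsions along the N-CA-CB-SG-SG'-CB'-CA'-N' chain of a cystine:
#' chi1 (N-CA-CB-SG), chi2 (CA-CB-SG-SG'), chi3 (CB-SG-SG'-CB', the
#' disulphide torsion), chi4 (SG-SG'-CB'-CA', equivalently chi2') and chi5
#' (SG'-CB'-CA'-N', equivalently chi1').
#'
#' @param structure A `protein_structure`.
#' @param bond A row of [detect_disulfides()] output (or a two-row residue
#'   reference of the two cysteines).
#' @return Named numeric vector `chi1`..`chi5` in degrees, range (-180, 180].
#' @export
chi_angles <- function(structure, bond) {
  refs <- .bond_refs(bond)
  need <- c("N", "CA", "CB", "SG")
  pick <- function(i) {
    at <- .residue_atoms(structure, refs[i, ])
    m <- lapply(need, function(nm) {
      row <- at[at$atom_name == nm, ]
      if (nrow(row) == 0) {
        stop_input(sprintf("chi_angles: atom %s missing from CYS %s%d", nm,
                           refs$chain_id[i], refs$res_seq[i]),
                   class = "ssphot_missing_atoms_error")
      }
      c(row$x[1], row$y[1], row$z[1])
    })
    setNames(m, need)
  }
  a <- pick(1)
  b <- pick(2)
  c(chi1 = dihedral_angle(a$N, a$CA, a$CB, a$SG),
    chi2 = dihedral_angle(a$CA, a$CB, a$SG, b$SG),
    chi3 = dihedral_angle(a$CB, a$SG, b$SG, b$CB),
    chi4 = dihedral_angle(a$SG, b$SG, b$CB, b$CA),
    chi5 = dihedral_angle(b$SG, b$CB, b$CA, b$N))
}

#' Classify disulphide stereochemistry from chi1-chi5
#'
#' The 20-class scheme used for allosteric-disulphide analysis: handedness
#' from the sign of chi3 (RH if positive), the Spiral/Hook/Staple motif from
#' the signs of chi2 and chi4 relative to chi3 (Spiral: both match chi3;
#' Staple: both oppose chi3; Hook: mixed), and a -, + or +/- prefix from the
#' signs of chi1 and chi5. The -RHStaple class is the geometry associated
#' with allosteric, photolysis-prone bonds.
#'
#' @param chi Numeric length-5 vector of dihedrals in degrees.
#' @return Label string such as `"-RHStaple"`, or `"unclassified"` when any
#'   angle is exactly zero (sign ambiguous).
#' @export
classify_geometry <- function(chi) {
  stopifnot(length(chi) == 5, all(is.finite(chi)))
  if (any(chi == 0)) {
    warn("classify_geometry: chi angle exactly zero; sign ambiguous")
    return("unclassified")
  }
  s <- sign(chi)
  handed <- if (s[3] > 0) "RH" else "LH"
  motif <- if (s[2] == s[3] && s[4] == s[3]) {
    "Spiral"
  } else if (s[2] == -s[3] && s[4] == -s[3]) {
    "Staple"
  } else {
    "Hook"
  }
  prefix <- if (s[1] < 0 && s[5] < 0) "-" else if (s[1] > 0 && s[5] > 0) "+" else "+/-"
  paste0(prefix, handed, motif)
}

#' Torsional strain energy of a cystine
#'
#' Approximate dihedral strain energy (kJ/mol) from the torsional potential
#' used in disulphide-analysis practice:
#' `E = 8.37(1+cos 3chi1) + 8.37(1+cos 3chi5) + 4.18(1+cos 3chi2)
#'    + 4.18(1+cos 3chi4) + 14.64(1+cos 2chi3) + 2.51(1+cos 3chi3)`.
#' Values are indicative of torsional stress, not a calibrated free energy.
#'
#' @param chi Numeric length-5 vector of dihedrals in degrees.
#' @return Energy in kJ/mol (>= 0).
#' @export
strain_energy <- function(chi) {
  stopifnot(length(chi) == 5, all(is.finite(chi)))
  r <- chi * pi / 180
  8.37 * (1 + cos(3 * r[1])) + 8.37 * (1 + cos(3 * r[5])) +
    4.18 * (1 + cos(3 * r[2])) + 4.18 * (1 + cos(3 * r[4])) +
    14.64 * (1 + cos(2 * r[3])) + 2.51 * (1 + cos(3 * r[3]))
}

#' Full disulphide bond table
#'
#' Detects bonds and annotates each with chi1-chi5, geometry class, strain
#' energy and (optionally) per-cysteine side-chain solvent accessibility.
#'
#' @param structure A `protein_structure`.
#' @param config An [analysis_config()].
#' @param asa Compute side-chain ASA columns (default TRUE; the ASA of a
#'   half-cystine is computed in the intact structure).
#' @return Tibble: [detect_disulfides()] columns plus `chi1`..`chi5`,
#'   `geometry_class`, `strain_energy`, and when `asa` is TRUE `asa_cys1`,
#'   `asa_cys2`, `asa_pct1`, `asa_pct2` (percent of the reference Cys area).
#' @export
analyze_disulfides <- function(structure, config = analysis_config(), asa = TRUE) {
  bonds <- detect_disulfides(structure, config)
  if (nrow(bonds) == 0) return(bonds)
  chis <- t(vapply(seq_len(nrow(bonds)),
                   function(i) chi_angles(structure, bonds[i, ]),
                   numeric(5)))
  colnames(chis) <- paste0("chi", 1:5)
  bonds <- bind_rows(lapply(seq_len(nrow(bonds)), function(i) bonds[i, ]))
  bonds <- cbind(bonds, as_tibble(chis))
  bonds$geometry_class <- vapply(seq_len(nrow(chis)),
                                 function(i) classify_geometry(chis[i, ]),
                                 character(1))
  bonds$strain_energy <- vapply(seq_len(nrow(chis)),
                                function(i) strain_energy(chis[i, ]),
                                numeric(1))
  bonds <- as_tibble(bonds)
  if (asa) {
    areas <- shrake_rupley_asa(structure, config)
    asa_tbl <- t(vapply(seq_len(nrow(bonds)), function(i) {
      unlist(cys_side_chain_asa(structure, bonds[i, ], config, areas = areas))
    }, numeric(4)))
    bonds$asa_cys1 <- asa_tbl[, "asa1"]
    bonds$asa_cys2 <- asa_tbl[, "asa2"]
    bonds$asa_pct1 <- asa_tbl[, "pct1"]
    bonds$asa_pct2 <- asa_tbl[, "pct2"]
  }
  bonds
}

.AA1 <- c(TRP = "W", TYR = "Y")

#' Aromatic-residue / disulphide proximity table
#'
#' Shortest ring-atom-to-cystine-atom distance for every (Trp or Tyr, bond)
#' pair, the screening step for photolysis-candidate disulphides.
#'
#' @param structure A `protein_structure`.
#' @param config An [analysis_config()].
#' @param cutoff Keep pairs with distance below this value (default `Inf`,
#'   i.e. all pairs; use 6 for contact tables, 12 for domain surveys).
#' @param convention Cystine atom-selection convention, see [cystine_atoms()].
#' @param bonds Optional precomputed [detect_disulfides()] table.
#' @return Tibble: `aromatic` (e.g. `"W761"`), `res_name`, `chain_id`,
#'   `res_seq`, `bond_id`, `distance`, `ring_atom`, `cystine_atom`, sorted by
#'   bond then residue.
#' @export
aromatic_ss_proximity <- function(structure, config = analysis_config(),
                                  cutoff = Inf,
                                  convention = c("all-atoms", "sidechain",
                                                 "sulfur-only"),
                                  bonds = NULL) {
  convention <- match.arg(convention)
  if (is.null(bonds)) bonds <- detect_disulfides(structure, config)
  res <- residues(structure)
  arom <- res[res$res_name %in% c("TRP", "TYR"), ]
  if (nrow(bonds) == 0 || nrow(arom) == 0) {
    return(tibble(aromatic = character(), res_name = character(),
                  chain_id = character(), res_seq = integer(),
                  bond_id = character(), distance = double(),
                  ring_atom = character(), cystine_atom = character()))
  }
  cys_sets <- lapply(seq_len(nrow(bonds)),
                     function(i) cystine_atoms(structure, bonds[i, ], convention))
  out <- list()
  for (r in seq_len(nrow(arom))) {
    ring <- ring_atoms(structure, arom[r, ])
    for (b in seq_len(nrow(bonds))) {
      md <- min_distance(ring, cys_sets[[b]])
      out[[length(out) + 1]] <- tibble(
        aromatic = paste0(.AA1[[arom$res_name[r]]], arom$res_seq[r]),
        res_name = arom$res_name[r],
        chain_id = arom$chain_id[r],
        res_seq = arom$res_seq[r],
        bond_id = bonds$bond_id[b],
        distance = md$distance,
        ring_atom = md$atom_a,
        cystine_atom = md$atom_b)
    }
  }
  out <- bind_rows(out)
  out <- out[out$distance < cutoff | is.infinite(cutoff), ]
  arrange(out, .data$bond_id, .data$res_seq)
}

#' Count aromatic residues near any disulphide
#'
#' @param structure A `protein_structure`.
#' @param config An [analysis_config()].
#' @param threshold Distance cutoff in Angstrom (strictly less than); default
#'   the config's `proximity_threshold` (8).
#' @param proximity Optional precomputed [aromatic_ss_proximity()] table
#'   (computed with `cutoff = Inf`).
#' @param ... Passed to [aromatic_ss_proximity()] when it must be computed.
#' @return One-row tibble: `n_trp`, `total_trp`, `n_tyr`, `total_tyr`,
#'   `threshold`.
#' @export
count_aromatics_near_ss <- function(structure, config = analysis_config(),
                                    threshold = config$proximity_threshold,
                                    proximity = NULL, ...) {
  if (is.null(proximity)) {
    proximity <- aromatic_ss_proximity(structure, config, cutoff = Inf, ...)
  }
  res <- residues(structure)
  totals <- table(factor(res$res_name, levels = c("TRP", "TYR")))
  nearest <- proximity |>
    group_by(.data$res_name, .data$chain_id, .data$res_seq) |>
    summarise(dmin = min(.data$distance), .groups = "drop")
  near <- nearest[nearest$dmin < threshold, ]
  tibble(n_trp = sum(near$res_name == "TRP"),
         total_trp = as.integer(totals[["TRP"]]),
         n_tyr = sum(near$res_name == "TYR"),
         total_tyr = as.integer(totals[["TYR"]]),
         threshold = threshold)
}

#' Tyrosine pair distances and crosslink clusters
#'
#' For every Tyr pair, the shortest distance between ortho carbons (CE1/CE2,
#' the dityrosine coupling positions). Pairs whose residues fall closer than
#' `config$tyr_cluster_threshold` under the clustering metric are grouped
#' into single-linkage clusters.
#'
#' @param structure A `protein_structure`.
#' @param config An [analysis_config()].
#' @param cluster_on Metric used for clustering: `"residue"` (default, the
#'   shortest distance between any heavy atoms of the two tyrosines),
#'   `"ring"` (ring atoms only) or `"ortho"` (the reported ortho-carbon
#'   distance itself).
#' @return Tibble with one row per Tyr pair: `tyr1`, `tyr2` (residue numbers,
#'   `tyr1 < tyr2`), `chain_id`, `distance` (ortho-carbon minimum),
#'   `cluster_distance` (metric used for clustering), `cluster_id` (integer
#'   id when both residues belong to the same cluster, `NA` otherwise).
#'   Cluster membership is available via [tyr_clusters()].
#' @export
tyr_pair_distances <- function(structure, config = analysis_config(),
                               cluster_on = c("residue", "ring", "ortho")) {
  cluster_on <- match.arg(cluster_on)
  res <- residues(structure)
  tyr <- res[res$res_name == "TYR", ]
  if (nrow(tyr) < 2) {
    stop_input("tyr_pair_distances needs at least two TYR residues")
  }
  ortho <- lapply(seq_len(nrow(tyr)), function(i) ortho_carbons(structure, tyr[i, ]))
  full <- lapply(seq_len(nrow(tyr)), function(i) {
    switch(cluster_on,
           residue = .residue_atoms(structure, tyr[i, ])[, c("atom_name", "x", "y", "z")],
           ring = ring_atoms(structure, tyr[i, ]),
           ortho = ortho[[i]])
  })
  pairs <- utils::combn(nrow(tyr), 2)
  out <- lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    tibble(tyr1 = tyr$res_seq[i], tyr2 = tyr$res_seq[j],
           chain_id = tyr$chain_id[i],
           distance = min_distance(ortho[[i]], ortho[[j]])$distance,
           cluster_distance = min_distance(full[[i]], full[[j]])$distance)
  })
  out <- bind_rows(out)

  # single-linkage components over pairs under the threshold
  edges <- out[out$cluster_distance < config$tyr_cluster_threshold, ]
  members <- tibble(res_seq = integer(), cluster_id = integer())
  out$cluster_id <- NA_integer_
  if (nrow(edges) > 0) {
    g <- igraph::graph_from_data_frame(
      data.frame(from = as.character(edges$tyr1), to = as.character(edges$tyr2)),
      directed = FALSE)
    comp <- igraph::components(g)$membership
    comp_tbl <- tibble(res_seq = as.integer(names(comp)), raw = as.integer(comp))
    relabel <- comp_tbl |>
      group_by(.data$raw) |>
      summarise(lead = min(.data$res_seq), .groups = "drop") |>
      arrange(.data$lead)
    relabel$cluster_id <- seq_len(nrow(relabel))
    comp_tbl <- left_join(comp_tbl, relabel[, c("raw", "cluster_id")], by = "raw")
    members <- arrange(comp_tbl[, c("res_seq", "cluster_id")], .data$cluster_id,
                       .data$res_seq)
    id1 <- members$cluster_id[match(out$tyr1, members$res_seq)]
    id2 <- members$cluster_id[match(out$tyr2, members$res_seq)]
    out$cluster_id <- ifelse(!is.na(id1) & !is.na(id2) & id1 == id2, id1,
                             NA_integer_)
  }
  out <- arrange(out, .data$tyr1, .data$tyr2)
  attr(out, "clusters") <- members
  out
}

#' Cluster membership from a tyrosine pair table
#'
#' @param pairs Output of [tyr_pair_distances()].
#' @return Tibble `res_seq`, `cluster_id`.
#' @export
tyr_clusters <- function(pairs) {
  attr(pairs, "clusters") %||% tibble(res_seq = integer(), cluster_id = integer())
}

#' Disulphide fraction of a protein chain
#'
#' 100 times the number of disulphide bridges divided by the chain length.
#'
#' @param n_ss Number of disulphide bonds.
#' @param n_res Chain length in amino acids.
#' @return Percentage.
#' @export
ss_fraction <- function(n_ss, n_res) {
  if (any(n_res <= 0)) stop_input("ss_fraction: chain length must be positive")
  100 * n_ss / n_res
}

#' Chain-length profile of disulphide fractions
#'
#' Bins a dataset of proteins by chain length and reports the mean disulphide
#' fraction per bin, the background against which a disulphide-rich protein
#' is judged.
#'
#' @param dataset Tibble/data frame with columns `n_ss` and `n_res`.
#' @param bin_width Chain-length bin width in residues (default 50).
#' @return Tibble `bin_lo`, `bin_hi`, `n_proteins`, `mean_fraction` (percent).
#' @export
ss_fraction_profile <- function(dataset, bin_width = 50) {
  stopifnot(nrow(dataset) > 0, all(c("n_ss", "n_res") %in% names(dataset)))
  frac <- ss_fraction(dataset$n_ss, dataset$n_res)
  bin <- floor((dataset$n_res - 1) / bin_width)
  out <- tibble(bin = bin, frac = frac) |>
    group_by(.data$bin) |>
    summarise(n_proteins = dplyr::n(), mean_fraction = mean(.data$frac),
              .groups = "drop") |>
    arrange(.data$bin)
  tibble(bin_lo = out$bin * bin_width + 1,
         bin_hi = (out$bin + 1) * bin_width,
         n_proteins = out$n_proteins,
         mean_fraction = out$mean_fraction)
}

#' Enrichment of a protein's disulphide fraction over its length bin
#'
#' @param profile Output of [ss_fraction_profile()].
#' @param n_ss,n_res Query protein bond count and chain length.
#' @param flag_ratio Enrichment ratio above which the query is flagged as an
#'   outlier (default 5).
#' @return One-row tibble: `fraction`, `bin_mean`, `ratio`, `outlier`.
#' @export
ss_fraction_enrichment <- function(profile, n_ss, n_res, flag_ratio = 5) {
  frac <- ss_fraction(n_ss, n_res)
  hit <- profile$bin_lo <= n_res & n_res <= profile$bin_hi
  if (!any(hit)) stop_input("query chain length falls outside the profile bins")
  bin_mean <- profile$mean_fraction[which(hit)[1]]
  ratio <- if (bin_mean > 0) frac / bin_mean else Inf
  tibble(fraction = frac, bin_mean = bin_mean, ratio = ratio,
         outlier = ratio >= flag_ratio)
}
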