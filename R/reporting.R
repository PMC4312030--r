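#' Run the full structural analysis of one structure
#'
#' The whole screening workflow on a single chain: disulphide detection and
#' stereochemistry, aromatic proximity, Tyr crosslink geometry and summary
#' counts — the per-structure evidence used to call photolysis-candidate
#' bonds.
#'
#' @param x A `protein_structure` or a path to a PDB file.
#' @param config An [analysis_config()].
#' @param chain Chain to analyse (default: chain with the most cysteines).
#' @param convention Cystine atom convention for proximity distances.
#' @param asa Compute per-cysteine ASA columns (slowest step; default TRUE).
#' @return List of class `ss_analysis`: `structure`, `bonds`, `proximity`,
#'   `counts`, `tyr_pairs` (NULL with fewer than 2 Tyr), `summary` (one-row
#'   tibble with `n_ss`, `n_res`, `ss_fraction`, aromatic counts).
#' @export
analyze_structure <- function(x, config = analysis_config(), chain = NULL,
                              convention = "all-atoms", asa = TRUE) {
  s <- if (inherits(x, "protein_structure")) x else read_structure(x)
  s <- select_chain(s, chain)
  bonds <- analyze_disulfides(s, config, asa = asa)
  prox <- aromatic_ss_proximity(s, config, cutoff = Inf,
                                convention = convention,
                                bonds = bonds[, intersect(names(bonds),
                                  c("bond_id", "cys1_chain", "cys1_res_seq",
                                    "cys1_icode", "cys2_chain", "cys2_res_seq",
                                    "cys2_icode", "sg_distance"))])
  counts <- count_aromatics_near_ss(s, config, proximity = prox)
  res <- residues(s)
  tyr_pairs <- if (sum(res$res_name == "TYR") >= 2) {
    tyr_pair_distances(s, config)
  } else NULL
  summary <- tibble(
    id = s$id,
    chain = s$provenance$chain %||% NA_character_,
    n_res = nrow(res),
    n_ss = nrow(bonds),
    ss_fraction = if (nrow(res) > 0) ss_fraction(nrow(bonds), nrow(res)) else NA_real_,
    n_trp = counts$total_trp, n_tyr = counts$total_tyr,
    n_trp_within = counts$n_trp, n_tyr_within = counts$n_tyr,
    threshold = counts$threshold)
  structure(list(structure = s, bonds = bonds, proximity = prox,
                 counts = counts, tyr_pairs = tyr_pairs, summary = summary),
            class = "ss_analysis")
}

#' @export
print.ss_analysis <- function(x, ...) {
  s <- x$summary
  cat("<ss_analysis> ", s$id, " chain ", s$chain, ": ", s$n_ss,
      " disulphides over ", s$n_res, " residues (",
      sprintf("%.1f%%", s$ss_fraction), ")\n", sep = "")
  cat("  Trp within ", s$threshold, " A of a bond: ", s$n_trp_within, "/",
      s$n_trp, "; Tyr: ", s$n_tyr_within, "/", s$n_tyr, "\n", sep = "")
  invisible(x)
}

.write_manifest <- function(out_dir, inputs, config, seed = NULL, extra = list()) {
  manifest <- c(list(
    package = "ssphotolysis",
    version = as.character(utils::packageVersion("ssphotolysis")),
    inputs = inputs,
    config = unclass(config),
    seed = seed), extra)
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  path
}

#' Write the structural report files
#'
#' Emits deterministic, re-run-identical TSV/JSON reports for one structure:
#' `ssbonds.tsv` (bond geometry, class, strain, ASA), `proximity.tsv`,
#' `tyr_pairs.tsv`, `summary.json` and `manifest.json`.
#'
#' @inheritParams analyze_structure
#' @param out_dir Output directory (created if needed).
#' @param near_cutoff Distance cutoff applied to the proximity table written
#'   to disk (default: keep all pairs).
#' @return Invisibly, the `ss_analysis` object (paths in attribute `paths`).
#' @export
report_structure <- function(x, out_dir, config = analysis_config(),
                             chain = NULL, convention = "all-atoms",
                             asa = TRUE, near_cutoff = Inf) {
  an <- analyze_structure(x, config, chain = chain, convention = convention,
                          asa = asa)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    ssbonds = file.path(out_dir, "ssbonds.tsv"),
    proximity = file.path(out_dir, "proximity.tsv"),
    tyr_pairs = file.path(out_dir, "tyr_pairs.tsv"),
    summary = file.path(out_dir, "summary.json"))
  readr::write_tsv(an$bonds, paths[["ssbonds"]])
  prox <- an$proximity
  prox <- prox[prox$distance < near_cutoff | is.infinite(near_cutoff), ]
  readr::write_tsv(prox, paths[["proximity"]])
  if (!is.null(an$tyr_pairs)) {
    readr::write_tsv(an$tyr_pairs, paths[["tyr_pairs"]])
  }
  jsonlite::write_json(as.list(an$summary), paths[["summary"]],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  inputs <- if (inherits(x, "protein_structure")) x$provenance$path %||% x$id else x
  .write_manifest(out_dir, inputs = inputs, config = config,
                  extra = list(convention = convention, chain = an$summary$chain))
  attr(an, "paths") <- paths
  invisible(an)
}

#' Fit a kinetic trace and write the result files
#'
#' @param x A trace tibble (columns `t`, `y`) or a path readable by
#'   [read_kinetic_trace()].
#' @param out_dir Output directory.
#' @param model_id `"exp_rise"` or `"exp_sat"`.
#' @param window Optional fit window (minutes).
#' @return Invisibly, the `photo_fit`. Writes `fit.json` (parameters, errors,
#'   R2, convergence flag) and `residuals.tsv`.
#' @export
report_kinetics <- function(x, out_dir, model_id = "exp_rise", window = NULL) {
  trace <- if (is.character(x)) read_kinetic_trace(x) else x
  fit <- fit_single_exponential(trace, model_id = model_id, window = window)
  .write_fit(fit, out_dir)
  invisible(fit)
}

#' Fit a melt curve and write the result files
#'
#' @param x A melt tibble (columns `temp`, `y`) or a path readable by
#'   [read_melt_curve()].
#' @param out_dir Output directory.
#' @param window Optional temperature window (degrees C).
#' @return Invisibly, the `photo_fit` (model `"boltzmann"`).
#' @export
report_melt <- function(x, out_dir, window = NULL) {
  curve <- if (is.character(x)) read_melt_curve(x) else x
  fit <- fit_boltzmann_melt(curve, window = window)
  .write_fit(fit, out_dir)
  invisible(fit)
}

.write_fit <- function(fit, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  payload <- list(model_id = fit$model_id,
                  params = as.list(fit$params),
                  stderr = as.list(fit$stderr),
                  r2 = fit$r2, converged = fit$converged,
                  window = fit$window, n = fit$n,
                  flag = fit$flag %||% NA_character_)
  jsonlite::write_json(payload, file.path(out_dir, "fit.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (fit$converged) {
    readr::write_tsv(fit$data, file.path(out_dir, "residuals.tsv"))
  }
}

#' Analyse an ensemble and write RMSF / exposure reports
#'
#' Superposes the ensemble, writes `rmsf.tsv`, and for the requested residues
#' `asa_dist.tsv` (unit-integral densities per residue). When a comparison
#' ensemble is given, also writes `comparison.json` with the per-residue RMSF
#' shifts and per-residue distribution overlap.
#'
#' @param x An `md_ensemble` or path to a multi-model PDB file.
#' @param out_dir Output directory.
#' @param residues Optional residue references for side-chain exposure.
#' @param compare Optional second ensemble (or path) to compare against.
#' @param selection RMSF/superposition selection (default `"calpha"`).
#' @param config An [analysis_config()].
#' @param bin_width Exposure histogram bin width (Angstrom^2).
#' @return Invisibly, a list with the computed tables.
#' @export
report_ensemble <- function(x, out_dir, residues = NULL, compare = NULL,
                            selection = "calpha",
                            config = analysis_config(), bin_width = 5) {
  ens <- if (is.character(x)) read_ensemble(x) else x
  if (n_frames(ens) < 2) {
    stop_input("ensemble analysis needs at least two frames")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ens <- superpose(ens, reference = "mean", selection = selection)
  prof <- rmsf(ens, selection = selection)
  readr::write_tsv(as_tibble(prof), file.path(out_dir, "rmsf.tsv"))
  out <- list(rmsf = prof)
  if (!is.null(residues)) {
    series <- sidechain_asa_series(ens, residues, config)
    dists <- series |>
      group_by(.data$chain_id, .data$res_seq, .data$res_name) |>
      tidyr::nest() |>
      ungroup()
    dist_tbl <- bind_rows(lapply(seq_len(nrow(dists)), function(i) {
      d <- asa_distribution(dists$data[[i]]$asa, bin_width = bin_width)
      mutate(as_tibble(d), chain_id = dists$chain_id[i],
             res_seq = dists$res_seq[i], res_name = dists$res_name[i])
    }))
    readr::write_tsv(dist_tbl, file.path(out_dir, "asa_dist.tsv"))
    out$asa_series <- series
    out$asa_dist <- dist_tbl
  }
  if (!is.null(compare)) {
    other <- if (is.character(compare)) read_ensemble(compare) else compare
    other <- superpose(other, reference = "mean", selection = selection)
    cmp <- compare_profiles(prof, rmsf(other, selection = selection))
    jsonlite::write_json(cmp, file.path(out_dir, "comparison.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    out$comparison <- cmp
  }
  .write_manifest(out_dir,
                  inputs = if (is.character(x)) x else ens$topology$id,
                  config = config,
                  extra = list(selection = selection, bin_width = bin_width))
  invisible(out)
}
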