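#' Build a structural ensemble
#'
#' An ensemble is a fixed topology (atom table) plus F congruent coordinate
#' frames, the container for multi-model PDB files or trajectory snapshots.
#'
#' @param topology A `protein_structure` providing the atom table (its own
#'   coordinates are frame 0 metadata only).
#' @param frames A list of n_atoms x 3 matrices, or an array of dimension
#'   `c(n_atoms, 3, F)`.
#' @param labels Optional frame labels.
#' @return An `md_ensemble`.
#' @export
as_ensemble <- function(topology, frames, labels = NULL) {
  if (is.list(frames)) {
    frames <- array(unlist(frames),
                    dim = c(nrow(frames[[1]]), 3, length(frames)))
  }
  stopifnot(length(dim(frames)) == 3, dim(frames)[2] == 3)
  if (dim(frames)[1] != nrow(topology$atoms)) {
    stop_input("frames and topology disagree on atom count")
  }
  structure(list(topology = topology, frames = frames,
                 labels = labels %||% paste0("frame", seq_len(dim(frames)[3]))),
            class = "md_ensemble")
}

#' @export
print.md_ensemble <- function(x, ...) {
  cat("<md_ensemble> ", x$topology$id, ": ", dim(x$frames)[1], " atoms x ",
      n_frames(x), " frames\n", sep = "")
  invisible(x)
}

#' Number of frames in an ensemble
#' @param ensemble An `md_ensemble`.
#' @return Integer frame count.
#' @export
n_frames <- function(ensemble) dim(ensemble$frames)[3]

#' Restrict an ensemble to a frame range
#'
#' Equilibration handling: analyses often discard the first part of a
#' trajectory; this keeps only the requested frames (default: all).
#'
#' @param ensemble An `md_ensemble`.
#' @param frames Integer vector of frame indices to keep.
#' @return The restricted `md_ensemble`.
#' @export
subset_frames <- function(ensemble, frames) {
  frames <- as.integer(frames)
  if (length(frames) == 0 || any(frames < 1 | frames > n_frames(ensemble))) {
    stop_input("frame indices out of range")
  }
  out <- ensemble
  out$frames <- ensemble$frames[, , frames, drop = FALSE]
  out$labels <- ensemble$labels[frames]
  out
}

#' Read a multi-model PDB file as an ensemble
#'
#' @param path PDB file with MODEL/ENDMDL records.
#' @param altloc_policy See [read_structure()].
#' @return An `md_ensemble` whose topology is model 1 with policies applied.
#' @export
read_ensemble <- function(path, altloc_policy = c("highest-occupancy", "label-A")) {
  altloc_policy <- match.arg(altloc_policy)
  topo <- read_structure(path, model_policy = "first",
                         altloc_policy = altloc_policy)
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                                          verbose = FALSE))
  keep <- match(topo$atoms$serial, as.integer(pdb$atom$eleno))
  nf <- nrow(pdb$xyz)
  frames <- lapply(seq_len(nf), function(m) {
    xyz <- matrix(pdb$xyz[m, ], ncol = 3, byrow = TRUE)
    xyz[keep, , drop = FALSE]
  })
  as_ensemble(topo, frames)
}

#' Write an ensemble as a multi-model PDB file
#'
#' @param ensemble An `md_ensemble`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(ensemble, path) {
  topo <- ensemble$topology
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp), add = TRUE)
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  for (m in seq_len(n_frames(ensemble))) {
    s <- topo
    s$atoms$x <- ensemble$frames[, 1, m]
    s$atoms$y <- ensemble$frames[, 2, m]
    s$atoms$z <- ensemble$frames[, 3, m]
    write_structure(s, tmp)
    lines <- readLines(tmp)
    lines <- lines[!grepl("^END\\s*$", lines)]
    writeLines(sprintf("MODEL     %4d", m), con)
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

# indices of the atoms used for superposition / per-residue statistics
.selection_idx <- function(topology, selection) {
  at <- topology$atoms
  idx <- switch(selection,
                calpha = which(at$type == "ATOM" & at$atom_name == "CA" & !at$is_h),
                heavy = which(at$type == "ATOM" & !at$is_h),
                all = seq_len(nrow(at)),
                stop_input("selection must be 'calpha', 'heavy' or 'all'"))
  if (length(idx) == 0) stop_input("empty atom selection")
  idx
}

# Kabsch: optimal proper rotation of b onto a (both centred)
.kabsch <- function(a, b) {
  h <- crossprod(b, a)
  sv <- svd(h)
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
}

#' Superpose ensemble frames onto a reference
#'
#' Rigid-body least-squares superposition (Kabsch) of every frame onto a
#' reference frame or onto the ensemble mean (one iteration against the mean
#' structure), fitted on a selection and applied to all atoms. Only proper
#' rotations are used, so mirror-image frames keep a positive RMSD.
#'
#' @param ensemble An `md_ensemble`.
#' @param reference Frame index, or `"mean"`.
#' @param selection `"calpha"` (default), `"heavy"` or `"all"`.
#' @return The superposed `md_ensemble`.
#' @export
superpose <- function(ensemble, reference = 1L, selection = "calpha") {
  idx <- .selection_idx(ensemble$topology, selection)
  if (length(idx) < 3) {
    stop_input("superposition needs at least three selected atoms",
               class = "ssphot_degeneracy_error")
  }
  fit_to <- function(frames, ref_sel) {
    ref_c <- colMeans(ref_sel)
    ref0 <- sweep(ref_sel, 2, ref_c)
    if (qr(ref0)$rank < 2) {
      stop_input("superposition selection is numerically degenerate (collinear)",
                 class = "ssphot_degeneracy_error")
    }
    for (m in seq_len(dim(frames)[3])) {
      mob <- frames[, , m]
      mob_sel <- mob[idx, , drop = FALSE]
      mc <- colMeans(mob_sel)
      rot <- .kabsch(ref0, sweep(mob_sel, 2, mc))
      frames[, , m] <- sweep(sweep(mob, 2, mc) %*% t(rot), 2, ref_c, "+")
    }
    frames
  }
  frames <- ensemble$frames
  if (identical(reference, "mean")) {
    frames <- fit_to(frames, frames[idx, , 1])
    mean_sel <- apply(frames[idx, , , drop = FALSE], c(1, 2), mean)
    frames <- fit_to(frames, mean_sel)
  } else {
    frames <- fit_to(frames, frames[idx, , as.integer(reference)])
  }
  out <- ensemble
  out$frames <- frames
  out
}

#' RMSD between two frames over a selection
#'
#' @param ensemble An `md_ensemble`.
#' @param i,j Frame indices.
#' @param selection Atom selection (see [superpose()]).
#' @return RMSD in Angstrom.
#' @export
frame_rmsd <- function(ensemble, i, j, selection = "calpha") {
  idx <- .selection_idx(ensemble$topology, selection)
  a <- ensemble$frames[idx, , i]
  b <- ensemble$frames[idx, , j]
  sqrt(mean(rowSums((a - b)^2)))
}

#' Per-residue root-mean-square fluctuations
#'
#' `RMSF_i = sqrt(mean_frames |x_i - <x_i>|^2)` per selected atom, averaged
#' within each residue. The ensemble should be superposed first.
#'
#' @param ensemble An `md_ensemble` (>= 2 frames).
#' @param selection `"calpha"` (default) or `"heavy"`.
#' @return A `fluctuation_profile` tibble: `chain_id`, `res_seq`, `res_name`,
#'   `rmsf` (Angstrom).
#' @export
rmsf <- function(ensemble, selection = "calpha") {
  if (n_frames(ensemble) < 2) {
    stop_input("RMSF needs at least two frames")
  }
  idx <- .selection_idx(ensemble$topology, selection)
  at <- ensemble$topology$atoms[idx, ]
  sub <- ensemble$frames[idx, , , drop = FALSE]
  mean_xyz <- apply(sub, c(1, 2), mean)
  dev2 <- apply(sub, 3, function(fr) rowSums((fr - mean_xyz)^2))
  atom_rmsf <- sqrt(rowMeans(matrix(dev2, nrow = length(idx))))
  out <- tibble(chain_id = at$chain_id, res_seq = at$res_seq,
                res_name = at$res_name, rmsf = atom_rmsf) |>
    group_by(.data$chain_id, .data$res_seq, .data$res_name) |>
    summarise(rmsf = mean(.data$rmsf), .groups = "drop") |>
    arrange(.data$chain_id, .data$res_seq)
  class(out) <- c("fluctuation_profile", class(out))
  attr(out, "selection") <- selection
  out
}

.BACKBONE <- c("N", "CA", "C", "O", "OXT")

#' Per-frame side-chain solvent accessibility
#'
#' Shrake-Rupley ASA computed on every frame; the side-chain area of each
#' requested residue (non-backbone heavy atoms) is summed per frame.
#'
#' @param ensemble An `md_ensemble`.
#' @param residues Residue references (rows of [residues()] or
#'   [residue_ref()]).
#' @param config An [analysis_config()].
#' @return Tibble: `frame`, `chain_id`, `res_seq`, `res_name`, `asa`.
#' @export
sidechain_asa_series <- function(ensemble, residues,
                                 config = analysis_config()) {
  topo <- ensemble$topology
  for (i in seq_len(nrow(residues))) {
    if (nrow(.residue_atoms(topo, residues[i, ])) == 0) {
      stop_input(sprintf("residue %s%d not present in topology",
                         residues$chain_id[i], residues$res_seq[i]))
    }
  }
  out <- list()
  for (m in seq_len(n_frames(ensemble))) {
    s <- topo
    s$atoms$x <- ensemble$frames[, 1, m]
    s$atoms$y <- ensemble$frames[, 2, m]
    s$atoms$z <- ensemble$frames[, 3, m]
    areas <- shrake_rupley_asa(s, config)
    for (i in seq_len(nrow(residues))) {
      sel <- areas$chain_id == residues$chain_id[i] &
        areas$res_seq == residues$res_seq[i] &
        areas$atom_name %notin% .BACKBONE
      out[[length(out) + 1]] <- tibble(
        frame = m,
        chain_id = residues$chain_id[i],
        res_seq = as.integer(residues$res_seq[i]),
        res_name = areas$res_name[sel][1],
        asa = sum(areas$asa[sel]))
    }
  }
  bind_rows(out)
}

#' Unit-integral histogram of an exposure series
#'
#' Histogram density of per-frame ASA values on bins aligned to zero, with
#' `sum(density * bin_width) == 1` exactly.
#'
#' @param series Numeric values (Angstrom^2).
#' @param bin_width Bin width in Angstrom^2 (default 5).
#' @return An `asa_distribution` tibble: `bin_lo`, `bin_hi`, `mid`,
#'   `density`; attributes `bin_width` and `n`.
#' @export
asa_distribution <- function(series, bin_width = 5) {
  if (length(series) == 0) stop_input("empty series")
  stopifnot(bin_width > 0)
  lo <- floor(min(series) / bin_width) * bin_width
  hi <- ceiling(max(series) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  breaks <- seq(lo, hi, by = bin_width)
  idx <- pmin(findInterval(series, breaks, left.open = FALSE), length(breaks) - 1)
  counts <- tabulate(idx, nbins = length(breaks) - 1)
  out <- tibble(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1],
                mid = (breaks[-length(breaks)] + breaks[-1]) / 2,
                density = counts / (length(series) * bin_width))
  class(out) <- c("asa_distribution", class(out))
  attr(out, "bin_width") <- bin_width
  attr(out, "n") <- length(series)
  out
}

#' Compare two fluctuation profiles or exposure distributions
#'
#' For fluctuation profiles: per-residue signed differences (`b - a`). For
#' ASA distributions: rebinned to a common grid, reporting the means, the
#' mean shift and the overlap coefficient
#' `sum(min(density_a, density_b)) * bin_width` (1 for identical, 0 for
#' disjoint distributions).
#'
#' @param a,b Two `fluctuation_profile`s or two `asa_distribution`s.
#' @return A tibble: per-residue rows with `rmsf_a`, `rmsf_b`, `diff` for
#'   profiles; one row with `mean_a`, `mean_b`, `mean_shift`, `overlap` for
#'   distributions.
#' @export
compare_profiles <- function(a, b) {
  if (inherits(a, "fluctuation_profile") && inherits(b, "fluctuation_profile")) {
    merged <- dplyr::inner_join(
      as_tibble(a), as_tibble(b),
      by = c("chain_id", "res_seq", "res_name"), suffix = c("_a", "_b"))
    if (nrow(merged) == 0) stop_input("profiles share no residues")
    merged$diff <- merged$rmsf_b - merged$rmsf_a
    return(merged)
  }
  if (inherits(a, "asa_distribution") && inherits(b, "asa_distribution")) {
    bw <- attr(a, "bin_width")
    if (!identical(bw, attr(b, "bin_width"))) {
      stop_input("distributions must share a bin width to be compared")
    }
    lo <- min(a$bin_lo, b$bin_lo)
    hi <- max(a$bin_hi, b$bin_hi)
    grid <- seq(lo, hi - bw / 2, by = bw)
    da <- db <- numeric(length(grid))
    da[match(a$bin_lo, grid)] <- a$density
    db[match(b$bin_lo, grid)] <- b$density
    mean_of <- function(d) sum((grid + bw / 2) * d * bw)
    return(tibble(mean_a = mean_of(da), mean_b = mean_of(db),
                  mean_shift = mean_of(db) - mean_of(da),
                  overlap = sum(pmin(da, db)) * bw))
  }
  stop_input("compare_profiles expects two fluctuation profiles or two ASA distributions")
}

#' Plot a fluctuation profile
#'
#' @param profile A `fluctuation_profile`.
#' @return A ggplot object.
#' @export
plot_rmsf <- function(profile) {
  ggplot(as_tibble(profile), aes(x = .data$res_seq, y = .data$rmsf)) +
    geom_line() + geom_point(size = 0.8) +
    labs(x = "residue", y = "RMSF (Å)")
}

#' Plot an ASA distribution
#'
#' @param object An `asa_distribution`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.asa_distribution <- function(object, ...) {
  ggplot(as_tibble(object), aes(x = .data$mid, y = .data$density)) +
    geom_col(width = attr(object, "bin_width"), fill = "grey70",
             colour = "grey30") +
    labs(x = "side-chain ASA (Å²)", y = "density")
}
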