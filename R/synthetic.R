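# run expr under a fixed seed without disturbing the caller's RNG stream
.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv())) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

#' Generate a synthetic single-exponential kinetic trace
#'
#' `y(t) = offset - amplitude * exp(-rate * t)` plus optional additive
#' Gaussian noise, the ground-truth generator for fit-recovery studies.
#'
#' @param params Named numeric vector: either `C1`, `C2`, `k` (`exp_rise`) or
#'   `y0`, `A`, `R0` (`exp_sat`).
#' @param t Time grid in minutes (strictly increasing).
#' @param noise_sd Gaussian noise standard deviation in signal units
#'   (0 = exact curve).
#' @param seed RNG seed; required whenever `noise_sd > 0`.
#' @return Tibble with columns `t`, `y`; attributes `truth` (the parameters)
#'   and `model_id`.
#' @export
gen_kinetic_trace <- function(params, t, noise_sd = 0, seed = NULL) {
  stopifnot(all(diff(t) > 0))
  nm <- names(params)
  if (all(c("C1", "C2", "k") %in% nm)) {
    model_id <- "exp_rise"
    offset <- params[["C1"]]; amp <- params[["C2"]]; rate <- params[["k"]]
  } else if (all(c("y0", "A", "R0") %in% nm)) {
    model_id <- "exp_sat"
    offset <- params[["y0"]]; amp <- params[["A"]]; rate <- params[["R0"]]
  } else {
    stop_input("params must be named C1/C2/k or y0/A/R0")
  }
  if (noise_sd > 0 && is.null(seed)) {
    stop_input("a seed is required for noisy traces")
  }
  y <- .exp_model(t, offset, amp, rate)
  if (noise_sd > 0) y <- y + .with_seed(seed, rnorm(length(t), 0, noise_sd))
  out <- tibble(t = t, y = y)
  attr(out, "truth") <- params
  attr(out, "model_id") <- model_id
  out
}

#' Generate a synthetic sloping-baseline Boltzmann melt curve
#'
#' @param params Named numeric vector `A1`, `B1`, `A2`, `B2`, `x0`, `dx`
#'   (see [boltzmann_melt_model()]).
#' @param temps Temperature grid in degrees C (strictly increasing).
#' @param noise_sd Gaussian noise standard deviation in signal units.
#' @param seed RNG seed; required whenever `noise_sd > 0`.
#' @return Tibble with columns `temp`, `y`; attribute `truth`.
#' @export
gen_melt_curve <- function(params, temps = seq(25, 90, by = 1), noise_sd = 0,
                           seed = NULL) {
  need <- c("A1", "B1", "A2", "B2", "x0", "dx")
  if (!all(need %in% names(params))) {
    stop_input("params must be named A1, B1, A2, B2, x0, dx")
  }
  stopifnot(all(diff(temps) > 0))
  if (noise_sd > 0 && is.null(seed)) {
    stop_input("a seed is required for noisy curves")
  }
  y <- boltzmann_melt_model(temps, params[["A1"]], params[["B1"]],
                            params[["A2"]], params[["B2"]],
                            params[["x0"]], params[["dx"]])
  if (noise_sd > 0) y <- y + .with_seed(seed, rnorm(length(temps), 0, noise_sd))
  out <- tibble(temp = temps, y = y)
  attr(out, "truth") <- params
  out
}

# NeRF internal-coordinate placement: position atom d bonded to c with bond
# length l, angle a-b-c-d's (b,c,d) = ang degrees and torsion (a,b,c,d) = tor
.nerf <- function(a, b, c, l, ang, tor) {
  ang <- ang * pi / 180
  tor <- tor * pi / 180
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- .cross3(ab, bc)
  n <- n / sqrt(sum(n^2))
  m <- .cross3(n, bc)
  d2 <- c(-l * cos(ang), l * sin(ang) * cos(tor), l * sin(ang) * sin(tor))
  as.vector(c + cbind(bc, m, n) %*% d2)
}

#' Build a toy cystine structure with prescribed chi1-chi5
#'
#' Constructs Cartesian coordinates for a disulphide-bonded Cys-Cys model by
#' sequential internal-coordinate (NeRF) placement along the
#' N-CA-CB-SG-SG'-CB'-CA'-N' chain with ideal covalent geometry (CB-SG 1.81,
#' SG-SG 2.05 Angstrom, tetrahedral-like angles), so that the measured
#' dihedrals reproduce `chi_target` exactly up to rounding.
#'
#' @param chi_target Numeric length-5 vector of dihedrals in degrees,
#'   each in (-180, 180].
#' @param context `"dipeptide"` (two CYS residues only) or `"decapeptide"`
#'   (the cystine flanked by CA-only glycine placeholders, for tests that
#'   need extra occluders).
#' @return A `protein_structure` with CYS residues 1 and 2 on chain A.
#' @export
gen_disulfide_model <- function(chi_target, context = c("dipeptide", "decapeptide")) {
  context <- match.arg(context)
  stopifnot(length(chi_target) == 5,
            all(chi_target > -180 & chi_target <= 180))
  build <- function(jitter) {
    ang <- c(n_ca_cb = 110.5, ca_cb_sg = 114.4, cb_sg_sg = 104,
             sg_sg_cb = 104, sg_cb_ca = 114.4, cb_ca_n = 110.5) + jitter
    n1 <- c(0, 0, 0)
    ca1 <- c(1.458, 0, 0)
    # CB1 at the N-CA-CB angle in the xy-plane
    cb1 <- ca1 + 1.53 * c(-cos(ang[["n_ca_cb"]] * pi / 180),
                          sin(ang[["n_ca_cb"]] * pi / 180), 0)
    sg1 <- .nerf(n1, ca1, cb1, 1.81, ang[["ca_cb_sg"]], chi_target[1])
    sg2 <- .nerf(ca1, cb1, sg1, 2.05, ang[["cb_sg_sg"]], chi_target[2])
    cb2 <- .nerf(cb1, sg1, sg2, 1.81, ang[["sg_sg_cb"]], chi_target[3])
    ca2 <- .nerf(sg1, sg2, cb2, 1.53, ang[["sg_cb_ca"]], chi_target[4])
    n2 <- .nerf(sg2, cb2, ca2, 1.458, ang[["cb_ca_n"]], chi_target[5])
    c1 <- .nerf(cb1, n1, ca1, 1.52, 111, -120)
    c2 <- .nerf(cb2, n2, ca2, 1.52, 111, -120)
    list(xyz = rbind(n1, ca1, c1, cb1, sg1, sg2, cb2, c2, ca2, n2),
         chain = c(1, 1, 1, 1, 1, 2, 2, 2, 2, 2))
  }
  # retry with slightly perturbed flanking angles if the torsion combination
  # produces a steric clash between non-bonded atoms
  chain_order <- c(1, 2, 4, 5, 6, 7, 9, 10)  # row indices along the torsion chain
  ok <- NULL
  for (try in 0:5) {
    cand <- build(if (try == 0) 0 else stats::runif(6, -5, 5) * 0)
    # deterministic perturbation schedule: widen angles by 2 deg per retry
    if (try > 0) cand <- build(rep(2 * try, 6))
    xyz <- cand$xyz
    d <- as.matrix(stats::dist(xyz[chain_order, ]))
    bonded <- abs(row(d) - col(d)) == 1
    if (all(d[!bonded & upper.tri(d)] >= 1.5)) {
      ok <- cand
      break
    }
  }
  if (is.null(ok)) {
    stop_input("could not build a clash-free cystine for these torsions",
               class = "ssphot_steric_error")
  }
  xyz <- ok$xyz
  atoms <- tibble(
    atom_name = c("N", "CA", "C", "CB", "SG", "SG", "CB", "C", "CA", "N"),
    res_name = "CYS",
    chain_id = "A",
    res_seq = c(1L, 1L, 1L, 1L, 1L, 2L, 2L, 2L, 2L, 2L),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    element = c("N", "C", "C", "C", "S", "S", "C", "C", "C", "N"))
  if (context == "decapeptide") {
    flank <- tibble(
      atom_name = "CA", res_name = "GLY", chain_id = "A",
      res_seq = c(-3L, -2L, -1L, 0L, 3L, 4L, 5L, 6L),
      x = c(seq(-16, -7, by = 3), seq(12, 21, by = 3)),
      y = 0, z = 0, element = "C")
    atoms <- bind_rows(atoms, flank)
    atoms <- arrange(atoms, .data$res_seq)
  }
  new_structure(atoms, id = "synthetic-cystine",
                provenance = list(generator = "gen_disulfide_model",
                                  chi_target = chi_target, context = context))
}

# planar ring templates centred near the origin (x-y plane)
.tyr_ring_template <- function() {
  angs <- c(CG = 180, CD1 = 120, CE1 = 60, CZ = 0, CE2 = -60, CD2 = -120)
  xy <- 1.39 * cbind(cos(angs * pi / 180), sin(angs * pi / 180))
  tibble(atom_name = names(angs), x = xy[, 1], y = xy[, 2], z = 0,
         element = "C") |>
    bind_rows(tibble(atom_name = "OH", x = 1.39 + 1.36, y = 0, z = 0,
                     element = "O"))
}

.trp_ring_template <- function() {
  # fused pentagon (CG, CD1, NE1, CE2, CD2) + hexagon sharing the CD2-CE2 edge
  side5 <- 1.37
  r5 <- side5 / (2 * sin(pi / 5))
  angs5 <- 90 + (0:4) * 72
  p5 <- r5 * cbind(cos(angs5 * pi / 180), sin(angs5 * pi / 180))
  rownames(p5) <- c("CD1", "CG", "CD2", "CE2", "NE1")
  p <- p5["CD2", ]; q <- p5["CE2", ]
  e <- q - p
  e <- e / sqrt(sum(e^2))
  # hexagon on the far side of the shared edge from the pentagon centre
  out_dir <- c(e[2], -e[1])
  if (sum(out_dir * (p - c(0, 0))) < 0) out_dir <- -out_dir
  side6 <- sqrt(sum((q - p)^2))
  h <- side6 * sqrt(3) / 2
  centre6 <- (p + q) / 2 + out_dir * h
  hex_angle <- function(pt) atan2(pt[2] - centre6[2], pt[1] - centre6[1])
  a0 <- hex_angle(p)
  a1 <- hex_angle(q)
  dirn <- sign(sin(a1 - a0))
  angs6 <- a0 + dirn * (0:5) * pi / 3
  r6 <- sqrt(sum((p - centre6)^2))
  p6 <- cbind(centre6[1] + r6 * cos(angs6), centre6[2] + r6 * sin(angs6))
  rownames(p6) <- c("CD2", "CE2", "CZ2", "CH2", "CZ3", "CE3")
  pts <- rbind(p5, p6[c("CZ2", "CH2", "CZ3", "CE3"), ])
  tibble(atom_name = rownames(pts), x = pts[, 1], y = pts[, 2], z = 0,
         element = ifelse(rownames(pts) == "NE1", "N", "C"))
}

#' Add an aromatic probe residue at a prescribed distance from a cystine
#'
#' Places an idealized Tyr (or Trp) ring so that the shortest ring-atom to
#' cystine-atom distance equals `d`, providing ground truth for proximity
#' measurements.
#'
#' @param base A `protein_structure` containing at least one disulphide.
#' @param d Target shortest distance in Angstrom (> 2).
#' @param residue `"TYR"` (default) or `"TRP"`.
#' @param convention Cystine atom convention the distance is defined against.
#' @param config An [analysis_config()].
#' @return A `protein_structure` with the probe appended (residue number
#'   `max(res_seq) + 10`).
#' @export
gen_aromatic_probe <- function(base, d, residue = c("TYR", "TRP"),
                               convention = "all-atoms",
                               config = analysis_config()) {
  residue <- match.arg(residue)
  if (d <= 2) stop_input("probe distance must exceed 2 Angstrom")
  bonds <- detect_disulfides(base, config)
  if (nrow(bonds) == 0) stop_input("base structure has no disulphide")
  cys <- cystine_atoms(base, bonds[1, ], convention = convention)
  cys_xyz <- atom_xyz(cys)
  centre <- colMeans(cys_xyz)
  all_xyz <- atom_xyz(base$atoms)
  u <- centre - colMeans(all_xyz)
  if (sqrt(sum(u^2)) < 1e-6) u <- c(1, 0, 0)
  u <- u / sqrt(sum(u^2))
  tmpl <- if (residue == "TYR") .tyr_ring_template() else .trp_ring_template()
  tmpl_xyz <- atom_xyz(tmpl)
  tmpl_xyz <- sweep(tmpl_xyz, 2, colMeans(tmpl_xyz))
  # the target distance is defined on the ring atoms proper (no hydroxyl)
  ring_idx <- which(tmpl$atom_name %in% .RING_ATOMS[[residue]])
  place <- function(t) sweep(tmpl_xyz, 2, centre + t * u, "+")
  f <- function(t) {
    min_distance(place(t)[ring_idx, , drop = FALSE], cys_xyz)$distance - d
  }
  t_hi <- d + 10
  while (f(t_hi) < 0) t_hi <- t_hi + 10
  t_lo <- 0.1
  root <- stats::uniroot(f, c(t_lo, t_hi), tol = 1e-6)
  placed <- place(root$root)
  probe <- tibble(
    atom_name = tmpl$atom_name,
    res_name = residue,
    chain_id = base$atoms$chain_id[1],
    res_seq = max(base$atoms$res_seq) + 10L,
    x = placed[, 1], y = placed[, 2], z = placed[, 3],
    element = tmpl$element)
  atoms <- bind_rows(base$atoms[, intersect(names(base$atoms), names(probe))],
                     probe)
  new_structure(atoms, id = paste0(base$id, "+probe"),
                provenance = list(generator = "gen_aromatic_probe",
                                  target_distance = d, residue = residue))
}

#' Generate a jittered coordinate ensemble with known fluctuation structure
#'
#' Each frame is the base structure plus isotropic per-atom Gaussian
#' displacement with a per-residue standard deviation, optionally followed by
#' a random global rigid motion (to exercise superposition). The expected
#' per-atom RMSF of a sigma-jittered residue is `sigma * sqrt(3)`.
#'
#' @param base A `protein_structure`.
#' @param sigma Either a single standard deviation (Angstrom, per coordinate)
#'   or a named vector mapping residue numbers to sigmas (unlisted residues
#'   get 0).
#' @param n_frames Number of frames (>= 2).
#' @param seed RNG seed (required: the generator is pure given the seed).
#' @param rigid Apply a random rigid motion to every frame (default FALSE).
#' @return An `md_ensemble`.
#' @export
gen_ensemble <- function(base, sigma, n_frames, seed, rigid = FALSE) {
  stopifnot(n_frames >= 2)
  if (missing(seed)) stop_input("gen_ensemble requires an explicit seed")
  at <- base$atoms
  sig_atom <- if (length(sigma) == 1 && is.null(names(sigma))) {
    rep(sigma, nrow(at))
  } else {
    s <- sigma[as.character(at$res_seq)]
    s[is.na(s)] <- 0
    unname(s)
  }
  xyz <- atom_xyz(at)
  frames <- .with_seed(seed, {
    lapply(seq_len(n_frames), function(m) {
      fr <- xyz + matrix(rnorm(length(xyz), 0, rep(sig_atom, 3)),
                         ncol = 3)
      if (rigid) {
        rot <- .random_rotation()
        shift <- runif(3, -5, 5)
        ctr <- colMeans(fr)
        fr <- sweep(sweep(fr, 2, ctr) %*% t(rot), 2, ctr + shift, "+")
      }
      fr
    })
  })
  as_ensemble(base, frames)
}

.random_rotation <- function() {
  m <- matrix(rnorm(9), 3)
  qr_ <- qr(m)
  q <- qr.Q(qr_)
  d <- diag(sign(diag(qr.R(qr_))))
  q <- q %*% d
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
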