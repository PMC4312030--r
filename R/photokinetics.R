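#' Photochemical constants
#'
#' Molar extinction coefficients used by the thiol and absorbance arithmetic:
#' TNB2- at 412 nm (Ellman's assay product), and the 280 nm contributions of
#' tryptophan, tyrosine and cystine used for protein extinction-coefficient
#' estimates; plus the disulphide count of human plasminogen.
#'
#' @param eps_tnb,eps_trp,eps_tyr,eps_cystine Extinction coefficients
#'   (M^-1 cm^-1).
#' @param n_ss_plasminogen Disulphide bond count of human plasminogen.
#' @return Named list of class `photo_constants`.
#' @export
photo_constants <- function(eps_tnb = 14150, eps_trp = 5500, eps_tyr = 1490,
                            eps_cystine = 125, n_ss_plasminogen = 24L) {
  stopifnot(eps_tnb > 0, eps_trp > 0, eps_tyr > 0, eps_cystine > 0,
            n_ss_plasminogen >= 0)
  structure(list(eps_tnb = eps_tnb, eps_trp = eps_trp, eps_tyr = eps_tyr,
                 eps_cystine = eps_cystine,
                 n_ss_plasminogen = as.integer(n_ss_plasminogen)),
            class = "photo_constants")
}

.exp_model <- function(t, offset, amplitude, rate) offset - amplitude * exp(-rate * t)

.param_names <- list(exp_rise = c("C1", "C2", "k"),
                     exp_sat = c("y0", "A", "R0"))

#' Fit a single-exponential kinetic model
#'
#' Both parameterizations are the same three-parameter family
#' `offset - amplitude * exp(-rate * t)`: `exp_rise` reports `C1`, `C2`, `k`
#' (fluorescence traces, `F(t) = C1 - C2 e^{-kt}`) and `exp_sat` reports
#' `y0`, `A`, `R0` (thiol formation, `y = y0 - A e^{-R0 t}`). Fitting is
#' Levenberg-Marquardt nonlinear least squares with three heuristic starts
#' (endpoint plateau, log-linearised slope, mid-range half-life); the best
#' converged start wins.
#'
#' @param trace Data frame with columns `t` (minutes) and `y` (signal), e.g.
#'   from [gen_kinetic_trace()] or [read_kinetic_trace()].
#' @param model_id `"exp_rise"` or `"exp_sat"` (parameter naming only).
#' @param window Optional numeric length-2 time range to fit on.
#' @return A `photo_fit` object; see [tidy.photo_fit()]/[glance.photo_fit()].
#'   Non-convergence is reported via `converged = FALSE`, not an error; a
#'   constant signal raises a degenerate-fit error.
#' @export
fit_single_exponential <- function(trace, model_id = c("exp_rise", "exp_sat"),
                                   window = NULL) {
  model_id <- match.arg(model_id)
  d <- .as_txy(trace)
  if (!is.null(window)) d <- d[d$t >= window[1] & d$t <= window[2], ]
  if (nrow(d) < 4) stop_input("fit needs at least 4 points in the window")
  if (stats::sd(d$y) == 0) {
    stop_input("signal is constant: exponential fit is degenerate",
               class = "ssphot_degenerate_fit_error")
  }
  starts <- .exp_starts(d)
  fit <- .best_nls(
    y ~ offset - amplitude * exp(-rate * t), data = d, starts = starts)
  .photo_fit(fit, model_id = model_id, data = d,
             rename = setNames(c("offset", "amplitude", "rate"),
                               .param_names[[model_id]]),
             window = window %||% range(d$t))
}

.exp_starts <- function(d) {
  n <- nrow(d)
  span <- diff(range(d$t))
  rising <- d$y[n] >= d$y[1]
  # 1: plateau from the endpoints
  s1 <- list(offset = d$y[n], amplitude = d$y[n] - d$y[1], rate = 3 / max(span, 1e-9))
  # 2: log-linearised decay of |offset - y|
  off <- if (rising) max(d$y) + 0.05 * abs(diff(range(d$y))) else
    min(d$y) - 0.05 * abs(diff(range(d$y)))
  resid <- abs(off - d$y)
  ok <- resid > 1e-12
  s2 <- s1
  if (sum(ok) >= 2) {
    sl <- unname(stats::coef(stats::lm(log(resid[ok]) ~ d$t[ok]))[2])
    if (is.finite(sl) && sl < 0) {
      s2 <- list(offset = off, amplitude = off - d$y[1], rate = -sl)
    }
  }
  # 3: half-life read at mid-range
  mid <- (d$y[1] + d$y[n]) / 2
  t_half <- d$t[which.min(abs(d$y - mid))]
  r3 <- if (t_half > min(d$t)) log(2) / (t_half - min(d$t)) else 1 / max(span, 1e-9)
  s3 <- list(offset = d$y[n], amplitude = d$y[n] - d$y[1], rate = r3)
  list(s1, s2, s3)
}

# run nlsLM over multiple starts, return best converged fit (or NULL)
.best_nls <- function(formula, data, starts, lower = NULL, upper = NULL) {
  best <- NULL
  for (s in starts) {
    f <- tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        formula, data = data, start = s,
        lower = lower %||% rep(-Inf, length(s)),
        upper = upper %||% rep(Inf, length(s)),
        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-10))),
      error = function(e) NULL)
    if (is.null(f)) next
    rss <- sum(stats::resid(f)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = f, rss = rss)
  }
  best
}

.photo_fit <- function(best, model_id, data, rename, window) {
  tss <- sum((data$y - mean(data$y))^2)
  if (is.null(best)) {
    est <- setNames(rep(NA_real_, length(rename)), names(rename))
    return(structure(list(model_id = model_id, params = est, stderr = est,
                          r2 = NA_real_, converged = FALSE, window = window,
                          n = nrow(data), data = data, fit = NULL),
                     class = "photo_fit"))
  }
  fit <- best$fit
  co <- summary(fit)$coefficients
  est <- setNames(co[rename, "Estimate"], names(rename))
  se <- setNames(co[rename, "Std. Error"], names(rename))
  data$fitted <- stats::fitted(fit)
  data$resid <- stats::resid(fit)
  structure(list(model_id = model_id, params = est, stderr = se,
                 r2 = 1 - best$rss / tss, converged = TRUE, window = window,
                 n = nrow(data), data = data, fit = fit),
            class = "photo_fit")
}

#' Sloping-baseline Boltzmann model for thermal melts
#'
#' `y = A2 + B2*x + ((A1 + B1*x) - (A2 + B2*x)) / (1 + exp((x - x0)/dx))`:
#' two linear baselines (native `A1 + B1*x`, unfolded `A2 + B2*x`) joined by
#' a cooperative sigmoid with midpoint `x0` (the melting temperature) and
#' width `dx`.
#'
#' @param x Temperature (degrees C).
#' @param A1,B1,A2,B2,x0,dx Model parameters.
#' @return Model value(s).
#' @export
boltzmann_melt_model <- function(x, A1, B1, A2, B2, x0, dx) {
  A2 + B2 * x + ((A1 + B1 * x) - (A2 + B2 * x)) / (1 + exp((x - x0) / dx))
}

#' Fit a modified-Boltzmann thermal unfolding curve
#'
#' Six-parameter sloping-baseline sigmoid fit of an ellipticity melt; `x0` is
#' reported as the melting temperature. Initialisation: `x0` from the
#' temperature of steepest change (finite differences), `dx = 1.5`, baselines
#' from linear fits of the first and last 20 percent of the window.
#'
#' @param curve Data frame with columns `temp` (degrees C, strictly
#'   increasing) and `y` (ellipticity), e.g. from [gen_melt_curve()] or
#'   [read_melt_curve()].
#' @param window Optional numeric length-2 temperature range (the usual far-UV
#'   fit uses 60-90 degrees C).
#' @return A `photo_fit` with parameters `A1`, `B1`, `A2`, `B2`, `x0`, `dx`.
#'   Non-convergence or a window without an interior inflection is flagged
#'   (`converged = FALSE` / `flag`), not an error.
#' @export
fit_boltzmann_melt <- function(curve, window = NULL) {
  d <- .as_txy(curve, xcol = "temp")
  names(d)[1] <- "x"
  if (!is.null(window)) d <- d[d$x >= window[1] & d$x <= window[2], ]
  if (nrow(d) < 8) stop_input("melt fit needs at least 8 points in the window")
  n <- nrow(d)
  # steepest finite-difference slope locates the transition
  slope <- diff(d$y) / diff(d$x)
  imax <- which.max(abs(slope))
  x0_init <- (d$x[imax] + d$x[imax + 1]) / 2
  interior <- imax > 1 && imax < (n - 1)
  k <- max(2L, ceiling(0.2 * n))
  base1 <- stats::coef(stats::lm(y ~ x, data = d[seq_len(k), ]))
  base2 <- stats::coef(stats::lm(y ~ x, data = d[(n - k + 1):n, ]))
  start <- list(A1 = unname(base1[1]), B1 = unname(base1[2]),
                A2 = unname(base2[1]), B2 = unname(base2[2]),
                x0 = x0_init, dx = 1.5)
  alt <- start
  alt$x0 <- mean(range(d$x))
  alt$dx <- diff(range(d$x)) / 10
  best <- .best_nls(y ~ boltzmann_melt_model(x, A1, B1, A2, B2, x0, dx),
                    data = d, starts = list(start, alt))
  rename <- setNames(c("A1", "B1", "A2", "B2", "x0", "dx"),
                     c("A1", "B1", "A2", "B2", "x0", "dx"))
  out <- .photo_fit(best, model_id = "boltzmann", data = d, rename = rename,
                    window = window %||% range(d$x))
  out$flag <- if (!interior) "no-interior-inflection" else NA_character_
  if (!interior) out$converged <- FALSE
  out
}

.as_txy <- function(obj, xcol = "t") {
  d <- as_tibble(obj)
  cand_x <- c(xcol, "t", "time", "time_min", "temp", "temp_C", "T")
  xname <- intersect(cand_x, names(d))[1]
  yname <- intersect(c("y", "signal"), names(d))[1]
  if (is.na(xname) || is.na(yname)) {
    stop_input("expected a two-column table with a time/temperature column and a signal column")
  }
  d <- tibble(t = as.numeric(d[[xname]]), y = as.numeric(d[[yname]]))
  if (any(diff(d$t) <= 0)) stop_input("time/temperature axis must be strictly increasing")
  if (xcol == "temp") names(d)[1] <- "temp"
  d
}

#' @export
print.photo_fit <- function(x, ...) {
  cat("<photo_fit> model:", x$model_id,
      " converged:", x$converged, "\n")
  if (x$converged) {
    est <- sprintf("%s = %.6g (se %.3g)", names(x$params), x$params, x$stderr)
    cat(" ", paste(est, collapse = "; "), "\n  R2 =", signif(x$r2, 5),
        " n =", x$n, "\n")
  }
  invisible(x)
}

#' Tidy a photo_fit
#'
#' @param x A `photo_fit`.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std.error`.
#' @export
tidy.photo_fit <- function(x, ...) {
  tibble(term = names(x$params), estimate = unname(x$params),
         std.error = unname(x$stderr))
}

#' One-row summary of a photo_fit
#'
#' @param x A `photo_fit`.
#' @param ... Unused.
#' @return Tibble with `model_id`, `r.squared`, `converged`, `nobs`.
#' @export
glance.photo_fit <- function(x, ...) {
  tibble(model_id = x$model_id, r.squared = x$r2, converged = x$converged,
         nobs = x$n)
}

#' Plot a photo_fit
#'
#' Observed points with the fitted curve overlaid.
#'
#' @param object A `photo_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.photo_fit <- function(object, ...) {
  d <- object$data
  xlab <- if (object$model_id == "boltzmann") "temperature (°C)" else "time (min)"
  names(d)[1] <- "xvar"
  p <- ggplot(d, aes(x = .data$xvar, y = .data$y)) +
    geom_point(shape = 1) +
    labs(x = xlab, y = "signal", title = paste("model:", object$model_id))
  if (object$converged) p <- p + geom_line(aes(y = .data$fitted), colour = "red")
  p
}

#' Free thiol concentration from Ellman's assay absorbance
#'
#' Beer-Lambert arithmetic on the TNB2- product absorbance at 412 nm.
#'
#' @param a412 Absorbance at 412 nm (>= 0).
#' @param pathlength Cuvette path length in cm (default 1).
#' @param constants A [photo_constants()].
#' @return Thiol concentration in micromolar.
#' @export
thiol_concentration <- function(a412, pathlength = 1,
                                constants = photo_constants()) {
  if (any(a412 < 0)) stop_input("absorbance must be non-negative")
  if (any(pathlength <= 0)) stop_input("path length must be positive")
  1e6 * a412 / (constants$eps_tnb * pathlength)
}

#' Theoretical maximum thiol concentration
#'
#' The thiol concentration expected if every disulphide in every protein
#' molecule were disrupted, at `sh_per_bond` free SH formed per broken bond
#' (one, when the second sulfur remains a radical).
#'
#' @param protein_conc Protein concentration (micromolar).
#' @param n_ss Disulphide bonds per molecule.
#' @param sh_per_bond Free SH groups formed per disrupted bond (default 1).
#' @return Concentration in micromolar.
#' @export
theoretical_max_thiol <- function(protein_conc, n_ss, sh_per_bond = 1) {
  stopifnot(protein_conc >= 0, n_ss >= 0, sh_per_bond >= 0)
  protein_conc * n_ss * sh_per_bond
}

#' Disulphide bonds disrupted per molecule
#'
#' Ratio of the fitted thiol plateau to the protein concentration; the floor
#' gives the minimum number of bonds broken in every molecule.
#'
#' @param y0_plateau Fitted maximum thiol concentration (micromolar).
#' @param protein_conc Protein concentration (micromolar).
#' @return One-row tibble: `ratio`, `n_bonds` (floor of the ratio).
#' @export
estimate_broken_bonds <- function(y0_plateau, protein_conc) {
  if (protein_conc <= 0) stop_input("protein concentration must be positive")
  ratio <- y0_plateau / protein_conc
  tibble(ratio = ratio, n_bonds = floor(ratio))
}

#' Molar ratio of two solutions
#'
#' Mole ratio of component A (volume in microliters, concentration in mM) to
#' component B (volume in mL, concentration in micromolar), the DTNB-over-
#' protein excess arithmetic of an Ellman assay setup.
#'
#' @param vol_a Volume of A in microliters.
#' @param conc_a Concentration of A in millimolar.
#' @param vol_b Volume of B in milliliters.
#' @param conc_b Concentration of B in micromolar.
#' @return Dimensionless mole ratio A/B.
#' @export
molar_ratio <- function(vol_a, conc_a, vol_b, conc_b) {
  stopifnot(vol_a > 0, conc_a > 0, vol_b > 0)
  if (conc_b <= 0) stop_input("denominator concentration must be positive")
  (vol_a * 1e-6 * conc_a * 1e-3) / (vol_b * 1e-3 * conc_b * 1e-6)
}

#' Protein molar extinction coefficient at 280 nm
#'
#' Chromophore-count estimate: `5500 * nTrp + 1490 * nTyr + 125 * nCystine`
#' (M^-1 cm^-1).
#'
#' @param n_trp,n_tyr,n_cystine Residue/bond counts.
#' @param constants A [photo_constants()].
#' @return Extinction coefficient (M^-1 cm^-1).
#' @export
extinction_coefficient <- function(n_trp, n_tyr, n_cystine,
                                   constants = photo_constants()) {
  stopifnot(n_trp >= 0, n_tyr >= 0, n_cystine >= 0)
  constants$eps_trp * n_trp + constants$eps_tyr * n_tyr +
    constants$eps_cystine * n_cystine
}

#' Mean residue ellipticity
#'
#' Converts a machine-units CD signal (millidegrees) to mean residue
#' ellipticity (deg cm^2 dmol^-1):
#' `[theta] = mdeg * MRW / (pathlength_mm * conc_mg_ml)`.
#'
#' @param mdeg Ellipticity signal in millidegrees.
#' @param mrw Mean residue weight (g/mol), see [mean_residue_weight()].
#' @param pathlength Path length in millimeters.
#' @param conc Protein concentration in mg/mL.
#' @return Mean residue ellipticity (deg cm^2 dmol^-1).
#' @export
mean_residue_ellipticity <- function(mdeg, mrw, pathlength, conc) {
  if (pathlength <= 0 || conc <= 0) {
    stop_input("path length and concentration must be positive")
  }
  mdeg * mrw / (pathlength * conc)
}

#' Mean residue weight
#'
#' Molecular weight divided by the number of backbone amides (`n_aa - 1` for
#' a non-acetylated protein).
#'
#' @param mw Molecular weight (g/mol).
#' @param n_aa Number of amino acids.
#' @return Mean residue weight (g/mol).
#' @export
mean_residue_weight <- function(mw, n_aa) {
  stopifnot(mw > 0)
  if (n_aa < 2) stop_input("need at least two residues")
  mw / (n_aa - 1)
}

#' Adjacent-averaging smoother
#'
#' Centered moving mean with an odd window. At the series edges the window is
#' clipped to the available points (`edge = "shrink"`, the default, output
#' length equals input length) or the unsmoothable edges are dropped
#' (`edge = "truncate"`).
#'
#' @param y Numeric series.
#' @param window Odd integer window (5, 7 and 9 are the usual spectrum
#'   choices).
#' @param edge `"shrink"` or `"truncate"`.
#' @return Smoothed numeric series.
#' @export
adjacent_average <- function(y, window, edge = c("shrink", "truncate")) {
  edge <- match.arg(edge)
  if (window %% 2 == 0) stop_input("smoothing window must be odd")
  n <- length(y)
  if (window > n) stop_input("smoothing window longer than series")
  h <- (window - 1) / 2
  out <- vapply(seq_len(n), function(i) {
    mean(y[max(1, i - h):min(n, i + h)])
  }, numeric(1))
  if (edge == "truncate") out <- out[(h + 1):(n - h)]
  out
}

#' Normalize a series to its maximum
#'
#' @param y Numeric series with positive maximum.
#' @return `y / max(y)`.
#' @export
normalize_to_max <- function(y) {
  m <- max(y)
  if (!is.finite(m) || m <= 0) stop_input("series maximum must be positive")
  y / m
}

#' Percent change between two values
#'
#' @param before,after Values; `before` must be non-zero.
#' @return `100 * (after - before) / before`.
#' @export
percent_change <- function(before, after) {
  if (any(before == 0)) stop_input("baseline value must be non-zero")
  100 * (after - before) / before
}

#' Read a two-column kinetic trace
#'
#' Delimited text (CSV/TSV autodetected) with a header; the first column is
#' time in minutes, the second the signal.
#'
#' @param path File path.
#' @return Tibble with columns `t`, `y`.
#' @export
read_kinetic_trace <- function(path) {
  if (!file.exists(path)) {
    stop_input(paste0("trace file not found: ", path), class = "ssphot_io_error")
  }
  d <- readr::read_delim(path, show_col_types = FALSE, trim_ws = TRUE)
  if (ncol(d) < 2) stop_input("trace file must have two columns")
  out <- tibble(t = as.numeric(d[[1]]), y = as.numeric(d[[2]]))
  if (any(!is.finite(out$t)) || any(!is.finite(out$y))) {
    stop_input("non-numeric values in trace file", class = "ssphot_parse_error")
  }
  if (any(diff(out$t) <= 0)) stop_input("time axis must be strictly increasing")
  out
}

#' Read a two-column melt curve
#'
#' Delimited text with a header; first column temperature in degrees C,
#' second the ellipticity signal.
#'
#' @param path File path.
#' @return Tibble with columns `temp`, `y`.
#' @export
read_melt_curve <- function(path) {
  d <- read_kinetic_trace(path)
  names(d) <- c("temp", "y")
  if (any(d$temp < 0 | d$temp > 120)) {
    stop_input("temperatures outside the physical 0-120 degrees C range")
  }
  d
}
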