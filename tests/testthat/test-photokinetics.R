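test_that("noiseless exponential traces are recovered to machine precision", {
  # rising 405 nm fluorescence trace, 10 s sampling over 45 min
  tr <- gen_kinetic_trace(c(C1 = 1.43, C2 = -0.43, k = 0.076),
                          t = seq(0, 45, by = 1 / 6))
  f <- fit_single_exponential(tr, "exp_rise")
  expect_true(f$converged)
  expect_equal(unname(f$params), c(1.43, -0.43, 0.076), tolerance = 1e-7)
  expect_gt(f$r2, 1 - 1e-12)
  # saturating thiol-formation curve on the sparse illumination schedule
  tr2 <- gen_kinetic_trace(c(y0 = 2.29, A = 3.78, R0 = 0.037),
                           t = c(0, 22.5, 45, 90, 112.5))
  f2 <- fit_single_exponential(tr2, "exp_sat")
  expect_equal(unname(f2$params), c(2.29, 3.78, 0.037), tolerance = 1e-7)
  # tidy/glance expose the broom-style views
  td <- tidy(f2)
  expect_equal(td$term, c("y0", "A", "R0"))
  expect_true(all(td$std.error >= 0))
  expect_equal(glance(f2)$nobs, 5L)
})

test_that("degenerate and under-sized inputs are rejected, non-convergence is flagged", {
  flat <- tibble::tibble(t = 0:10, y = rep(1, 11))
  expect_error(fit_single_exponential(flat), class = "ssphot_degenerate_fit_error")
  expect_error(fit_single_exponential(tibble::tibble(t = 0:2, y = c(1, 2, 3))),
               class = "ssphot_input_error")
  expect_error(fit_boltzmann_melt(tibble::tibble(temp = 1:5, y = rnorm(5))),
               class = "ssphot_input_error")
})

test_that("near-linear traces produce ill-conditioned fits with honest errors", {
  # a slow quasi-linear decay (rate ~ 0) cannot pin down offset vs amplitude:
  # the fit may converge, but the reported uncertainties must expose it
  tr <- gen_kinetic_trace(c(C1 = 7.37, C2 = 6.37, k = -3.49e-4),
                          t = seq(0, 30, by = 1 / 6), noise_sd = 0.002,
                          seed = 12)
  f <- fit_single_exponential(tr, "exp_rise")
  if (f$converged) {
    rel <- abs(f$stderr / f$params)
    expect_gt(max(rel, na.rm = TRUE), 1)
  } else {
    expect_false(f$converged)
  }
})

test_that("fit is invariant under time-axis shift up to the amplitude re-parameterization", {
  tr <- gen_kinetic_trace(c(C1 = 1.43, C2 = -0.43, k = 0.076),
                          t = seq(0, 45, by = 0.5))
  f0 <- fit_single_exponential(tr, "exp_rise")
  shift <- 10
  tr2 <- tr
  tr2$t <- tr2$t + shift
  f1 <- fit_single_exponential(tr2, "exp_rise")
  expect_equal(f1$params[["k"]], f0$params[["k"]], tolerance = 1e-6)
  expect_equal(f1$params[["C1"]], f0$params[["C1"]], tolerance = 1e-6)
  # amplitude absorbs the shift: C2' = C2 * exp(k * shift)
  expect_equal(f1$params[["C2"]],
               f0$params[["C2"]] * exp(f0$params[["k"]] * shift),
               tolerance = 1e-5)
})

test_that("Boltzmann melt fits recover the midpoint and satisfy the midpoint identity", {
  pars <- c(A1 = 109.94, B1 = 50.89, A2 = -1.18, B2 = 0.016,
            x0 = 70.61, dx = 1.36)
  curve <- gen_melt_curve(pars, temps = seq(25, 90, by = 1))
  fit <- fit_boltzmann_melt(curve, window = c(60, 90))
  expect_true(fit$converged)
  expect_equal(fit$params[["x0"]], 70.61, tolerance = 0.05 / 70.61)
  expect_equal(unname(fit$params), unname(pars), tolerance = 1e-4)
  # flat-baseline midpoint identity: y(x0) = (A1 + A2) / 2
  expect_equal(boltzmann_melt_model(70, A1 = 1, B1 = 0, A2 = 0, B2 = 0,
                                    x0 = 70, dx = 1.5), 0.5)
  # recovery under 2% noise: small bias in the mean over seeds
  sd2 <- 0.02 * diff(range(curve$y[curve$temp >= 60]))
  x0s <- vapply(1:40, function(i) {
    noisy <- gen_melt_curve(pars, temps = seq(25, 90, by = 1),
                            noise_sd = sd2, seed = 5000 + i)
    fit_boltzmann_melt(noisy, window = c(60, 90))$params[["x0"]]
  }, numeric(1))
  expect_lt(abs(mean(x0s) - 70.61), 0.1)
})

test_that("Ellman and extinction arithmetic reproduce the published conversions", {
  expect_equal(thiol_concentration(0.0324, 1), 2.29, tolerance = 1e-3)
  expect_equal(thiol_concentration(0), 0)
  expect_equal(thiol_concentration(0.1, 2), thiol_concentration(0.1, 1) / 2)
  expect_error(thiol_concentration(-0.1), class = "ssphot_input_error")

  expect_equal(theoretical_max_thiol(0.97, 24), 23.28, tolerance = 1e-6)
  expect_equal(round(theoretical_max_thiol(0.97, 24), 1), 23.3)
  expect_equal(theoretical_max_thiol(1, 0), 0)
  expect_equal(theoretical_max_thiol(0.97, 24, 2), 2 * theoretical_max_thiol(0.97, 24))

  bb <- estimate_broken_bonds(2.29, 0.97)
  expect_equal(bb$ratio, 2.29 / 0.97)
  expect_equal(bb$n_bonds, 2)
  expect_equal(estimate_broken_bonds(0.5, 1)$n_bonds, 0)
  expect_equal(estimate_broken_bonds(24 * 0.97, 0.97)$n_bonds, 24)

  expect_equal(round(molar_ratio(10, 100, 1, 0.97)), 1031)
  expect_equal(molar_ratio(5, 2, 1, 10), 1)      # equal moles
  expect_equal(molar_ratio(100, 1000, 10, 9.7), molar_ratio(10, 100, 1, 0.97))

  expect_equal(extinction_coefficient(19, 30, 24), 152200)
  expect_equal(extinction_coefficient(0, 0, 0), 0)
  expect_equal(extinction_coefficient(1, 0, 0), 5500)

  expect_equal(mean_residue_ellipticity(10, 110, 1, 1), 1100)
  expect_equal(mean_residue_ellipticity(-10, 110, 1, 1), -1100)
  expect_equal(mean_residue_weight(100000, 768), 100000 / 767)

  # thiol pipeline round-trip: concentration -> A412 -> concentration
  conc <- 2.29
  a412 <- conc * 1e-6 * 14150
  expect_equal(thiol_concentration(a412), conc, tolerance = 1e-12)
})

test_that("adjacent averaging clips windows at the edges and preserves range", {
  expect_equal(adjacent_average(c(1, 2, 3, 4, 5), 3), c(1.5, 2, 3, 4, 4.5))
  expect_equal(adjacent_average(c(0, 0, 1, 0, 0), 5),
               c(1 / 3, 1 / 4, 1 / 5, 1 / 4, 1 / 3))
  expect_equal(adjacent_average(rep(7, 9), 5), rep(7, 9))
  expect_error(adjacent_average(1:10, 4), class = "ssphot_input_error")
  expect_error(adjacent_average(1:3, 5), class = "ssphot_input_error")
  y <- cumsum(rnorm(50))
  sm <- adjacent_average(y, 7)
  expect_true(all(sm >= min(y) & sm <= max(y)))
  expect_equal(length(adjacent_average(y, 7, edge = "truncate")), 44)
})

test_that("normalization and percent-change operators behave linearly", {
  expect_equal(normalize_to_max(c(2, 4)), c(0.5, 1))
  expect_error(normalize_to_max(c(-1, 0)), class = "ssphot_input_error")
  expect_equal(percent_change(100, 90.6), -9.4)
  expect_equal(percent_change(100, 244.3), 144.3)
  expect_error(percent_change(0, 10), class = "ssphot_input_error")
})

test_that("trace and melt files round-trip through the two-column readers", {
  f <- withr::local_tempfile(fileext = ".csv")
  tr <- gen_kinetic_trace(c(C1 = 1, C2 = -0.5, k = 0.1), t = seq(0, 30, 5))
  readr::write_csv(tr, f)
  back <- read_kinetic_trace(f)
  expect_equal(back$t, tr$t)
  expect_equal(back$y, tr$y)
  expect_error(read_kinetic_trace(file.path(tempdir(), "absent.csv")),
               class = "ssphot_io_error")
  fm <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("temp_C\tsignal", "25\t1.0", "30\t0.9", "26\t0.8"), fm)
  expect_error(read_melt_curve(fm), class = "ssphot_input_error")
})
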