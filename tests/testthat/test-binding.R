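test_that("KD from rates reproduces the kinetic characterization table", {
  for (i in seq_len(nrow(table5_rates))) {
    expect_equal(kd_from_rates(table5_rates$kon[i], table5_rates$koff[i]),
                 table5_rates$KD[i], tolerance = 1e-9,
                 info = table5_rates$sybody[i])
  }
  expect_equal(kd_from_rates(1, 1), 1)
  expect_error(kd_from_rates(0, 1), "positive")
  expect_error(kd_from_rates(1e5, -1), "positive")
})

test_that("simulated sensorgrams follow the 1:1 closed form", {
  kon <- 2e5; koff <- 1e-2; Rmax <- 120; KD <- koff / kon
  # zero analyte: identically zero response
  z <- simulate_sensorgram(kon, koff, Rmax, 0)
  expect_true(all(z$response == 0))
  # association plateaus on the binding isotherm Rmax*C/(C+KD)
  for (C in KD * c(1 / 9, 1 / 3, 1, 3, 9)) {
    g <- simulate_sensorgram(kon, koff, Rmax, C, t_assoc = 6000, t_dissoc = 10)
    plateau <- max(g$response[g$phase == "association"])
    expect_equal(plateau, Rmax * C / (C + KD), tolerance = 1e-10)
  }
  # half-saturation at C = KD
  g <- simulate_sensorgram(kon, koff, Rmax, KD, t_assoc = 6000, t_dissoc = 10)
  expect_equal(max(g$response), Rmax / 2, tolerance = 1e-10)
  # phases are continuous at the boundary
  g <- simulate_sensorgram(kon, koff, Rmax, KD, t_assoc = 100, t_dissoc = 100,
                           dt = 0.1)
  ia <- which(g$phase == "association")
  jump <- abs(g$response[max(ia) + 1L] - g$response[max(ia)])
  step <- max(abs(diff(g$response[g$phase == "dissociation"])))
  expect_lt(jump, 2 * step + 1e-12)
  # noise is seeded and reproducible
  n1 <- simulate_sensorgram(kon, koff, Rmax, KD, noise_sd = 1, seed = 3)
  n2 <- simulate_sensorgram(kon, koff, Rmax, KD, noise_sd = 1, seed = 3)
  expect_identical(n1, n2)
  expect_error(simulate_sensorgram(kon, koff, Rmax, KD, t_assoc = -5),
               "positive")
})

test_that("global 1:1 fits recover generating parameters from noiseless data", {
  kon <- 1.86e5; koff <- 7.44e-3; Rmax <- 100
  g <- simulate_sensorgram(kon, koff, Rmax, c(1, 3, 9, 27, 81) * 1e-9)
  fit <- fit_1to1(g)
  expect_true(fit$converged)
  expect_equal(fit$estimate$kon, kon, tolerance = 1e-6)
  expect_equal(fit$estimate$koff, koff, tolerance = 1e-6)
  expect_equal(fit$estimate$KD, koff / kon, tolerance = 1e-6)
  expect_equal(fit$estimate$Rmax, Rmax, tolerance = 1e-6)
  expect_false(is.null(fit$se))
  # a flat zero sensorgram is flagged, never silently fitted
  flat <- data.frame(time = 0:100, response = 0, concentration = 1e-9,
                     phase = "association")
  expect_false(fit_1to1(flat)$converged)
})

test_that("the Schild competition model has the designed analytic properties", {
  B <- 1e-6; alpha <- 0.017
  expect_equal(schild_ratio(0, B, alpha), 1)
  x <- seq(0, 1e-3, length.out = 200)
  expect_true(all(diff(schild_ratio(x, B, alpha)) > 0))
  expect_equal(schild_ratio(Inf, B, alpha), 1 / alpha)
  expect_equal(schild_ratio(1e3, B, alpha), 1 / alpha, tolerance = 1e-4)
  # substituting x = B gives 2/(1 + alpha)
  expect_equal(schild_ratio(B, B, alpha), 2 / (1 + alpha), tolerance = 1e-12)
  # no competition: ratio identically 1 when alpha = 1
  expect_true(all(abs(schild_ratio(x, B, 1) - 1) < 1e-12))
})

test_that("Schild fits recover B and alpha from the maltose-series design", {
  x <- c(0, 5, 10, 25, 50, 100) * 1e-6
  fit <- fit_schild(x, schild_ratio(x, 1e-6, 0.017))
  expect_true(fit$converged)
  expect_equal(fit$estimate$B, 1e-6, tolerance = 1e-6)
  expect_equal(fit$estimate$alpha, 0.017, tolerance = 1e-6)
  expect_equal(fit$estimate$saturating_ratio, 1 / 0.017, tolerance = 1e-6)
  # flat ratios at 1: alpha -> 1 (no competition)
  flat <- fit_schild(x, rep(1, 6))
  expect_equal(flat$estimate$alpha, 1)
})

test_that("hyperbolic inhibition fits recover y0, a and IC50", {
  y0 <- 20; a <- 80; ic50 <- 62e-9
  expect_equal(inhibition_curve(0, y0, a, ic50), y0 + a)
  expect_equal(inhibition_curve(ic50, y0, a, ic50), y0 + a / 2)
  expect_equal(inhibition_curve(1e5, y0, a, ic50), y0, tolerance = 1e-3)
  x <- c(0, 3^(0:7)) * 1e-9
  fit <- fit_inhibition(x, inhibition_curve(x, y0, a, ic50))
  expect_true(fit$converged)
  expect_equal(fit$estimate$y0, y0, tolerance = 1e-6)
  expect_equal(fit$estimate$a, a, tolerance = 1e-6)
  expect_equal(fit$estimate$IC50, ic50, tolerance = 1e-6)
  expect_false(fit_inhibition(x, rep(100, length(x)))$converged)
})

test_that("Boltzmann melt fits recover Tm and reproduce melting shifts", {
  temp <- seq(30, 60, length.out = 12)
  bottom <- 0.1; top <- 1; Tm <- 45; slope <- -1.5
  # the curve passes through the midpoint at T = Tm
  expect_equal(boltzmann_curve(Tm, bottom, top, Tm, slope),
               (bottom + top) / 2)
  fit <- fit_melt(temp, boltzmann_curve(temp, bottom, top, Tm, slope))
  expect_true(fit$converged)
  expect_equal(fit$estimate$Tm, Tm, tolerance = 1e-6)
  # an increasing transition (e.g. thermofluor direction) also fits
  fit_up <- fit_melt(temp, boltzmann_curve(temp, bottom, top, Tm, 1.5))
  expect_true(fit_up$converged)
  expect_equal(fit_up$estimate$Tm, Tm, tolerance = 1e-6)
  # a constructed stabilization shift in the reported regime is returned
  for (shift in c(6.1, 8.8, 10)) {
    f_apo <- fit_melt(temp, boltzmann_curve(temp, bottom, top, 40, slope))
    f_holo <- fit_melt(temp, boltzmann_curve(temp, bottom, top, 40 + shift,
                                             slope))
    expect_equal(delta_tm(f_holo, f_apo), shift, tolerance = 1e-6)
  }
  # flat curve: non-convergence flag, and delta_tm refuses to use it
  flat <- fit_melt(temp, rep(0.5, 12))
  expect_false(flat$converged)
  expect_error(delta_tm(fit, flat), "did not converge")
})
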