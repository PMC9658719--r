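test_that("solution coefficient from a single measurement is A/(c d)", {
  w <- c(500, 600)
  s <- concentration_series(list(hb_spectrum(w, c(0.5, 0.25), "absorbance")),
                            c_total = 5e-5, glycated_fraction = 0.5)
  eps <- epsilon_solution_from_series(s)
  expect_equal(eps$value, c(10000, 5000))
  expect_identical(eps$kind, "molar_absorption")
})

test_that("exact Beer-Lambert series gives the slope with zero residual", {
  w <- 500:510
  eps_true <- seq(1e4, 2e4, length.out = length(w))
  conc <- c(7, 6, 5, 4, 3) * 1e-5
  spectra <- lapply(conc, function(cc)
    hb_spectrum(w, eps_true * cc * 1, "absorbance"))
  s <- concentration_series(spectra, conc, glycated_fraction = 0.5)
  fit <- epsilon_solution_from_series(s)
  expect_equal(fit$value, eps_true, tolerance = 1e-12)
  expect_lt(max(attr(fit, "residual_sd")), 1e-12)
  # the mean-ratio estimator agrees on exact data
  mr <- epsilon_solution_from_series(s, method = "mean_ratio")
  expect_equal(mr$value, eps_true, tolerance = 1e-12)
  expect_error(concentration_series(spectra, rep(5e-5, 5), 0.5), "distinct")
})

test_that("noisy series estimates stay within 3 standard errors of truth", {
  set.seed(11)
  w <- seq(500, 600, 5)
  eps_true <- rep(1.5e4, length(w))
  conc <- c(7, 6, 5, 4, 3) * 1e-5
  sd_noise <- 0.005
  se <- sd_noise / sqrt(sum(conc^2))   # analytic no-intercept OLS slope se
  n_runs <- 60
  err <- matrix(NA_real_, n_runs, length(w))
  for (r in seq_len(n_runs)) {
    spectra <- lapply(conc, function(cc)
      hb_spectrum(w, eps_true * cc + rnorm(length(w), sd = sd_noise),
                  "absorbance"))
    fit <- epsilon_solution_from_series(
      concentration_series(spectra, conc, glycated_fraction = 0.5))
    err[r, ] <- fit$value - eps_true
  }
  rmse <- sqrt(colMeans(err^2))
  expect_true(all(rmse < 3 * se))
  expect_gt(mean(rmse), 0.5 * se)  # noise is actually propagating
})

test_that("glycated fraction is the concentration quotient", {
  expect_equal(hba1c_fraction(1, 1), 1)
  expect_equal(hba1c_fraction(0.5, 1), 0.5)
  expect_equal(hba1c_fraction(0.228e-3, 9.43e-3), 0.228 / 9.43)
  expect_equal(glycated_fraction_level("level1"), 0.228 / 9.43)
  expect_equal(glycated_fraction_level("level2"), 0.488 / 7.44)
  expect_error(hba1c_fraction(2, 1), "exceeds")
  expect_error(hba1c_fraction(-1, 1), "positive")
})

test_that("mixture correction inverts the forward model exactly", {
  w <- 450:700
  eps_a1c <- gaussian_band_spectrum(hb_band_preset("level1"), w)
  eps_non <- gaussian_band_spectrum(hb_band_preset("nonglycated"), w)
  for (f in c(glycated_fraction_level("level1"),
              glycated_fraction_level("level2"), 0.5, 1.0)) {
    eps_sol <- hb_spectrum(w, f * eps_a1c$value + (1 - f) * eps_non$value,
                           "molar_absorption")
    back <- correct_for_nonglycated(eps_sol, eps_non, f)
    expect_lt(max(abs(back$value - eps_a1c$value) / eps_a1c$value), 1e-12)
  }
  # limiting cases
  eps_sol <- hb_spectrum(w, eps_a1c$value, "molar_absorption")
  expect_identical(correct_for_nonglycated(eps_sol, eps_non, 1)$value,
                   eps_sol$value)
  zero_non <- hb_spectrum(w, rep(0, length(w)), "molar_absorption")
  expect_equal(correct_for_nonglycated(eps_sol, zero_non, 0.25)$value,
               eps_sol$value / 0.25)
  expect_error(correct_for_nonglycated(eps_sol, eps_non, 0), "\\(0, 1\\]")
  expect_error(correct_for_nonglycated(eps_sol, eps_non, 1.5), "\\(0, 1\\]")
})

test_that("corrected spectrum decreases in f when the solution absorbs less than the reference", {
  w <- c(500, 550)
  eps_sol <- hb_spectrum(w, c(100, 200), "molar_absorption")
  eps_non <- hb_spectrum(w, c(300, 400), "molar_absorption")
  fs <- seq(0.1, 1, by = 0.1)
  vals <- vapply(fs, function(f)
    correct_for_nonglycated(eps_sol, eps_non, f)$value[1], numeric(1))
  expect_true(all(diff(vals) > 0) || all(diff(vals) < 0))
  # eps_sol < eps_non everywhere: corrected value rises toward eps_sol as f -> 1
  expect_true(all(diff(vals) > 0))
})

test_that("Q-band peak detection reports the two strongest separated maxima", {
  g <- wavelength_grid(450, 700)
  two <- gaussian_band_spectrum(band_model(c(545, 579), 10, c(2, 1.5)), g)
  pk <- find_q_band_peaks(two)
  expect_equal(pk$wavelength_nm, c(545, 579))
  # invariance under positive rescaling
  pk10 <- find_q_band_peaks(
    hb_spectrum(two$wavelength, 10 * two$value, "molar_absorption"))
  expect_equal(pk10$wavelength_nm, pk$wavelength_nm)
  expect_equal(pk10$epsilon, 10 * pk$epsilon)
  # monotone spectrum: no local maxima
  mono <- hb_spectrum(450:700, seq(1, 2, length.out = 251), "molar_absorption")
  expect_warning(pk0 <- find_q_band_peaks(mono), "fewer")
  expect_equal(nrow(pk0), 0)
  # single band: shorter report with a warning
  one <- gaussian_band_spectrum(band_model(550, 10, 1), g)
  expect_warning(pk1 <- find_q_band_peaks(one), "1 local")
  expect_equal(pk1$wavelength_nm, 550)
  expect_error(find_q_band_peaks(two, window = c(600, 500)), "lo < hi")
  # minimum separation suppresses shoulder maxima of one cluster
  cl <- gaussian_band_spectrum(band_model(c(540, 548, 579), c(3, 3, 8),
                                          c(2, 1.9, 1.5)), g)
  pkc <- find_q_band_peaks(cl)
  expect_equal(nrow(pkc), 2)
  expect_true(all(diff(pkc$wavelength_nm) >= 10))
})

test_that("experimental pipeline recovers the generator truth noiselessly", {
  for (level in c("level1", "level2")) {
    tr <- make_truth(level)
    sim <- simulate_measurement_series(tr$eps_a1c, tr$eps_non, tr$f,
                                       noise_sd = 0, replicates = 3, seed = 5)
    fit <- run_experimental_pipeline(sim$replicates, tr$eps_non, tr$f)
    truth_band <- restrict_band(tr$eps_a1c, 450, 700)
    expect_lt(max(abs(fit$epsilon$value - truth_band$value) / truth_band$value),
              1e-9)
    centers <- hb_band_preset(level)$centers_nm
    expect_equal(fit$peaks$wavelength_nm, centers)
  }
})

test_that("pipeline with f = 1 returns the band-restricted solution spectrum", {
  tr <- make_truth("level1")
  sim <- simulate_measurement_series(tr$eps_a1c, tr$eps_non, 1,
                                     noise_sd = 0, replicates = 1, seed = 2)
  # eps_non is arbitrary here; it must not affect the f = 1 result
  arbitrary_non <- hb_spectrum(tr$eps_non$wavelength,
                               rev(tr$eps_non$value) + 1, "molar_absorption")
  fit <- run_experimental_pipeline(sim$replicates, arbitrary_non, f = 1)
  truth_band <- restrict_band(tr$eps_a1c, 450, 700)
  expect_equal(fit$epsilon$value, truth_band$value, tolerance = 1e-9)
})

test_that("pipeline recovers peaks within 2 nm under measurement noise", {
  tr <- make_truth("level1")
  sim <- simulate_measurement_series(tr$eps_a1c, tr$eps_non, tr$f,
                                     noise_sd = 0.002, replicates = 3, seed = 31)
  fit <- run_experimental_pipeline(sim$replicates, tr$eps_non, tr$f)
  expect_equal(nrow(fit$peaks), 2)
  expect_lt(max(abs(fit$peaks$wavelength_nm - c(545, 579))), 2 + 1e-9)
})
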