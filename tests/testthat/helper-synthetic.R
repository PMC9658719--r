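# Shared fixture builders. All randomness is seeded inside each test.

test_grid <- function(lo = 440, hi = 710, step = 1) wavelength_grid(lo, hi, step)

# ground truth + matching non-glycated reference on a common grid
make_truth <- function(level = "level1", grid = test_grid()) {
  list(eps_a1c = gaussian_band_spectrum(hb_band_preset(level), grid),
       eps_non = gaussian_band_spectrum(hb_band_preset("nonglycated"), grid),
       f = glycated_fraction_level(level))
}

# random valid %T spectrum on a fixed-size grid
random_pct_spectrum <- function(n = 50) {
  w <- sort(stats::runif(n, 300, 1100))
  while (any(diff(w) <= 0)) w <- sort(stats::runif(n, 300, 1100))
  hb_spectrum(w, stats::runif(n, 1e-3, 100), "percent_transmittance")
}

# mixture spectrum and the %T pair that the theoretical route consumes
make_theoretical_inputs <- function(level = "level1", c_total = 5e-5,
                                    grid = test_grid(), k = 1) {
  tr <- make_truth(level, grid)
  mix_val <- tr$f * tr$eps_a1c$value + (1 - tr$f) * tr$eps_non$value
  mix <- hb_spectrum(tr$eps_a1c$wavelength, mix_val, "molar_absorption")
  A <- hb_spectrum(mix$wavelength, k * mix_val * c_total, "absorbance")
  list(mix = mix,
       sol_T = absorbance_to_transmittance(A),
       solvent_T = hb_spectrum(mix$wavelength,
                               rep(100, length(mix$wavelength)),
                               "percent_transmittance"),
       truth = tr)
}

eps_at <- function(s, wl) {
  stats::approx(s$wavelength, s$value, xout = wl)$y
}
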