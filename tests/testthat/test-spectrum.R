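test_that("spectrum constructor enforces its invariants", {
  expect_s3_class(hb_spectrum(c(450, 451), c(1, 2), "absorbance"), "hb_spectrum")
  expect_error(hb_spectrum(450, 1, "absorbance"), "at least 2")
  expect_error(hb_spectrum(c(451, 450), c(1, 2), "absorbance"), "increasing")
  expect_error(hb_spectrum(c(450, 450), c(1, 2), "absorbance"), "increasing")
  expect_error(hb_spectrum(c(-1, 450), c(1, 2), "absorbance"), "positive")
  expect_error(hb_spectrum(c(450, 451), c(1, NA), "absorbance"), "finite")
  expect_error(hb_spectrum(c(450, 451), c(0, 50), "percent_transmittance"),
               "450")
  expect_error(hb_spectrum(c(450, 451), c(101, 50), "percent_transmittance"),
               "\\(0, 100\\]")
})

test_that("transmittance converts to absorbance as 2 - log10(%T)", {
  w <- c(500, 550, 600, 650)
  s <- hb_spectrum(w, c(100, 1, 10, 50), "percent_transmittance")
  a <- transmittance_to_absorbance(s)
  expect_identical(a$kind, "absorbance")
  expect_identical(a$wavelength, s$wavelength)
  expect_equal(a$value[1:3], c(0, 2, 1))
  expect_equal(a$value[4], 0.3010300, tolerance = 1e-7)
  expect_error(transmittance_to_absorbance(a), "expected a percent_transmittance")
})

test_that("absorbance converts back to %T, rejecting negatives by default", {
  a <- hb_spectrum(c(500, 600), c(0, 2), "absorbance")
  t <- absorbance_to_transmittance(a)
  expect_equal(t$value, c(100, 1))
  t50 <- absorbance_to_transmittance(
    hb_spectrum(c(500, 600), c(0.3010300, 0.3010300), "absorbance"))
  expect_equal(t50$value, c(50, 50), tolerance = 1e-6)
  neg <- hb_spectrum(c(500, 600), c(-0.01, 0.5), "absorbance")
  expect_error(absorbance_to_transmittance(neg), "500 nm")
  flagged <- absorbance_to_transmittance(neg, allow_negative = TRUE)
  expect_gt(flagged$value[1], 100)
  expect_true("transmittance_above_100" %in% attr(flagged, "flags"))
})

test_that("%T -> A -> %T round trip is identity within 1e-12 relative", {
  set.seed(42)
  for (i in 1:25) {
    s <- random_pct_spectrum()
    back <- absorbance_to_transmittance(transmittance_to_absorbance(s))
    expect_lt(max(abs(back$value - s$value) / s$value), 1e-12)
  }
})

test_that("absorbance is strictly decreasing in %T", {
  pct <- seq(0.5, 100, by = 0.5)
  a <- transmittance_to_absorbance(
    hb_spectrum(seq_along(pct) + 300, pct, "percent_transmittance"))
  expect_true(all(diff(a$value) < 0))
})

test_that("resampling interpolates linearly without extrapolation", {
  s <- hb_spectrum(seq(400, 500, 10), seq(400, 500, 10) * 2 + 1, "absorbance")
  same <- resample_spectrum(s, s$wavelength)
  expect_identical(same$value, s$value)
  # affine spectra are reproduced exactly at any interior grid
  fine <- resample_spectrum(s, seq(405, 495, 5))
  expect_equal(fine$value, seq(405, 495, 5) * 2 + 1)
  # quadratic: midpoint error equals the second-difference bound (h^2/8 * f'')
  q <- hb_spectrum(seq(400, 500, 10), (seq(400, 500, 10) - 450)^2, "absorbance")
  mid <- resample_spectrum(q, seq(405, 495, 10))
  truth <- (seq(405, 495, 10) - 450)^2
  expect_equal(mid$value - truth, rep(10^2 / 8 * 2, 10))
  expect_error(resample_spectrum(s, c(390, 450)), "outside the spectrum span")
  expect_error(resample_spectrum(s, c(450, 510)), "outside the spectrum span")
})

test_that("absorbance subtraction is pointwise with preserved negatives", {
  w <- c(500, 550, 600)
  a <- hb_spectrum(w, c(1.2, 0.8, 0.3), "absorbance")
  b <- hb_spectrum(w, c(0.2, 0.9, 0.1), "absorbance")
  d <- subtract_absorbance(a, b)
  expect_equal(d$value, c(1.0, -0.1, 0.2))
  expect_true("negative_values" %in% attr(d, "flags"))
  expect_equal(subtract_absorbance(a, a)$value, c(0, 0, 0))
  # group inverse: (a - b) + b == a
  expect_equal(d$value + b$value, a$value, tolerance = 1e-15)
  shifted <- hb_spectrum(w + 1, b$value, "absorbance")
  expect_error(subtract_absorbance(a, shifted), "different wavelength grids")
})

test_that("replicate averaging returns the mean with sample sd", {
  w <- c(500, 600)
  one <- hb_spectrum(w, c(1, 2), "absorbance")
  avg1 <- average_replicates(list(one))
  expect_equal(avg1$value, one$value)
  expect_equal(avg1$sd, c(0, 0))
  sym <- average_replicates(list(hb_spectrum(w, c(1, 2), "absorbance"),
                                 hb_spectrum(w, c(-1, -2), "absorbance")))
  expect_equal(sym$value, c(0, 0))
  three <- average_replicates(list(hb_spectrum(w, c(1, 1), "absorbance"),
                                   hb_spectrum(w, c(2, 2), "absorbance"),
                                   hb_spectrum(w, c(3, 3), "absorbance")))
  expect_equal(three$value, c(2, 2))
  expect_equal(three$sd, c(1, 1))
  # n identical copies: the spectrum itself, zero dispersion
  same <- average_replicates(rep(list(one), 5))
  expect_equal(same$value, one$value)
  expect_equal(same$sd, c(0, 0))
  expect_error(average_replicates(list(one,
    hb_spectrum(w, c(50, 60), "percent_transmittance"))), "mixed kinds")
})

test_that("band restriction keeps samples inside the limits", {
  s <- hb_spectrum(seq(300, 1100, 1), rep(1, 801), "absorbance")
  r <- restrict_band(s, 450, 700)
  expect_gte(min(r$wavelength), 450)
  expect_lte(max(r$wavelength), 700)
  expect_equal(length(r$wavelength), 251)
  whole <- restrict_band(s, 200, 1200)
  expect_identical(whole$wavelength, s$wavelength)
  expect_error(restrict_band(s, 1200, 1300), "does not intersect")
  # a band catching a single sample violates the >= 2 sample invariant
  expect_error(restrict_band(s, 500, 500.5), "at least 2")
})

test_that("spectra round-trip through the CSV dialect", {
  s <- hb_spectrum(c(450.25, 500, 700), c(0.123456789, 1, 2), "absorbance")
  path <- tempfile(fileext = ".csv")
  write_spectrum(s, path)
  expect_match(readLines(path)[1], "# kind: absorbance")
  back <- read_spectrum(path)
  expect_identical(back$kind, "absorbance")
  expect_equal(back$wavelength, s$wavelength)
  expect_equal(back$value, s$value, tolerance = 1e-8)
  # repeated writes are bit-stable
  path2 <- tempfile(fileext = ".csv")
  write_spectrum(back, path2)
  expect_identical(readLines(path), readLines(path2))
  expect_error(read_spectrum(textConnection("x")), "")
})
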