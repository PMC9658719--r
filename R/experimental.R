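#' Composition of one measured cuvette
#'
#' @param c_total Total hemoglobin concentration in mol/L (> 0).
#' @param glycated_fraction Molar fraction of glycated hemoglobin in
#'   (0, 1].
#' @param path_length Cuvette path length in cm (> 0), default 1 cm.
#' @param label Free-text label (e.g. `"level 1"`).
#' @return An object of class `solution_composition`.
#' @export
solution_composition <- function(c_total, glycated_fraction,
                                 path_length = 1, label = "") {
  if (!is.finite(c_total) || c_total <= 0)
    stop("c_total must be positive (mol/L)", call. = FALSE)
  if (!is.finite(glycated_fraction) || glycated_fraction <= 0 ||
      glycated_fraction > 1)
    stop("glycated_fraction must lie in (0, 1]", call. = FALSE)
  if (!is.finite(path_length) || path_length <= 0)
    stop("path_length must be positive (cm)", call. = FALSE)
  structure(list(c_total = c_total, glycated_fraction = glycated_fraction,
                 path_length = path_length, label = as.character(label)),
            class = "solution_composition")
}

#' Concentration series of absorbance spectra
#'
#' Bundles absorbance spectra measured at several total-hemoglobin
#' concentrations sharing the glycated fraction, path length, and
#' wavelength grid — the dilution-series design used to estimate a molar
#' absorption coefficient by regression through the origin.
#'
#' @param spectra List of absorbance spectra on identical grids, one per
#'   concentration.
#' @param c_total Numeric vector of total hemoglobin concentrations in
#'   mol/L, same length as `spectra`, all distinct when more than one.
#' @param glycated_fraction Shared glycated molar fraction in (0, 1].
#' @param path_length Shared cuvette path length in cm.
#' @param labels Optional character labels per member.
#' @return An object of class `concentration_series`.
#' @export
concentration_series <- function(spectra, c_total, glycated_fraction,
                                 path_length = 1, labels = NULL) {
  if (!is.list(spectra) || length(spectra) < 1L)
    stop("spectra must be a non-empty list", call. = FALSE)
  if (length(c_total) != length(spectra))
    stop("c_total must match spectra in length", call. = FALSE)
  if (any(!is.finite(c_total)) || any(c_total <= 0))
    stop("concentrations must be positive (mol/L)", call. = FALSE)
  if (length(c_total) > 1L && anyDuplicated(c_total))
    stop("concentrations must be distinct", call. = FALSE)
  for (s in spectra) assert_kind(s, "absorbance")
  for (s in spectra[-1L]) assert_same_grid(spectra[[1L]], s)
  # composition validation (fraction/path ranges)
  solution_composition(c_total[1L], glycated_fraction, path_length)
  structure(list(spectra = spectra, c_total = as.numeric(c_total),
                 glycated_fraction = glycated_fraction,
                 path_length = path_length,
                 labels = labels %||% rep("", length(spectra))),
            class = "concentration_series")
}

#' @export
print.concentration_series <- function(x, ...) {
  cat(sprintf("<concentration_series> %d concentrations (%s mmol/L), f = %.5g, d = %g cm\n",
              length(x$c_total),
              paste(signif(1e3 * sort(x$c_total), 3), collapse = ", "),
              x$glycated_fraction, x$path_length))
  invisible(x)
}

#' Solution molar absorption spectrum from a concentration series
#'
#' At each wavelength the Beer-Lambert law forces `A = eps * c * d` with
#' zero intercept, so the solution coefficient is estimated as the slope
#' of the no-intercept least-squares fit of absorbance against `c * d`
#' across the series. For a single member this reduces to
#' `eps = A / (c * d)`. A per-wavelength residual standard deviation and
#' the analytic standard error of the slope
#' (`se = sigma / sqrt(sum((c*d)^2))`) are attached as attributes. The
#' mean-ratio estimator (the average of the per-concentration
#' `A / (c * d)`) is available for comparison.
#'
#' @param series A [concentration_series()].
#' @param method `"ols"` (default) or `"mean_ratio"`.
#' @return A `molar_absorption` spectrum with attributes `residual_sd`
#'   and `slope_se` (both `NA` for a single-member series or the
#'   mean-ratio estimator).
#' @export
epsilon_solution_from_series <- function(series, method = c("ols", "mean_ratio")) {
  method <- match.arg(method)
  if (!inherits(series, "concentration_series"))
    stop("series must be a concentration_series", call. = FALSE)
  x <- series$c_total * series$path_length
  A <- vapply(series$spectra, `[[`,
              numeric(length(series$spectra[[1L]]$value)), "value")
  A <- matrix(A, ncol = length(x))
  if (method == "mean_ratio") {
    eps <- rowMeans(sweep(A, 2L, x, "/"))
    out <- hb_spectrum(series$spectra[[1L]]$wavelength, eps, "molar_absorption")
    attr(out, "residual_sd") <- rep(NA_real_, length(eps))
    attr(out, "slope_se") <- rep(NA_real_, length(eps))
    return(out)
  }
  sxx <- sum(x^2)
  eps <- as.vector(A %*% x) / sxx
  n <- length(x)
  if (n > 1L) {
    resid <- A - outer(eps, x)
    sigma2 <- rowSums(resid^2) / (n - 1)
    residual_sd <- sqrt(sigma2)
    slope_se <- sqrt(sigma2 / sxx)
  } else {
    residual_sd <- rep(NA_real_, length(eps))
    slope_se <- rep(NA_real_, length(eps))
  }
  out <- hb_spectrum(series$spectra[[1L]]$wavelength, eps, "molar_absorption")
  attr(out, "residual_sd") <- residual_sd
  attr(out, "slope_se") <- slope_se
  out
}

#' Glycated molar fraction from component concentrations
#'
#' @param c_hba1c Glycated hemoglobin concentration, mol/L.
#' @param c_total Total hemoglobin concentration, mol/L; must be >=
#'   `c_hba1c`.
#' @return The fraction `c_hba1c / c_total` in (0, 1].
#' @examples
#' hba1c_fraction(0.228e-3, 9.43e-3)  # level-1 control material
#' @export
hba1c_fraction <- function(c_hba1c, c_total) {
  if (!is.finite(c_hba1c) || !is.finite(c_total) || c_hba1c <= 0 || c_total <= 0)
    stop("concentrations must be positive and finite", call. = FALSE)
  if (c_hba1c > c_total)
    stop("c_hba1c exceeds c_total: impossible composition", call. = FALSE)
  c_hba1c / c_total
}

#' Default glycated fractions of the bilevel control material
#'
#' The two levels of the lyophilized whole-blood control used here have
#' stated total hemoglobin contents of 9.43 and 7.44 mmol/L and HbA1c
#' contents of 0.228 and 0.488 mmol/L; the glycated molar fractions are
#' computed from those concentrations at call time (never stored as
#' decimals).
#'
#' @param level `"level1"` or `"level2"`.
#' @return The glycated molar fraction.
#' @examples
#' glycated_fraction_level("level1")  # 0.228/9.43
#' @export
glycated_fraction_level <- function(level = c("level1", "level2")) {
  level <- match.arg(level)
  switch(level,
         level1 = hba1c_fraction(0.228e-3, 9.43e-3),
         level2 = hba1c_fraction(0.488e-3, 7.44e-3))
}

#' Remove the non-glycated hemoglobin contribution
#'
#' The solution coefficient of a two-component hemoglobin mixture is
#' `eps_sol = f * eps_HbA1c + (1 - f) * eps_non` with `f` the glycated
#' molar fraction; this solves for the glycated component:
#' `eps_HbA1c = (eps_sol - (1 - f) * eps_non) / f`, the exact algebraic
#' inverse of the forward mixture. Negative outputs (possible under
#' noise when `f` is small) are preserved and flagged.
#'
#' @param eps_sol Solution molar absorption spectrum.
#' @param eps_non Non-glycated hemoglobin molar absorption spectrum on
#'   the same grid (a literature reference table in real use).
#' @param f Glycated molar fraction in (0, 1].
#' @return The glycated-hemoglobin molar absorption spectrum.
#' @export
correct_for_nonglycated <- function(eps_sol, eps_non, f) {
  assert_kind(eps_sol, "molar_absorption")
  assert_kind(eps_non, "molar_absorption")
  assert_same_grid(eps_sol, eps_non)
  if (!is.finite(f) || f <= 0 || f > 1)
    stop("glycated fraction f must lie in (0, 1]", call. = FALSE)
  v <- (eps_sol$value - eps_non$value * (1 - f)) / f
  flags <- if (any(v < 0)) "negative_values" else character()
  hb_spectrum(eps_sol$wavelength, v, "molar_absorption", flags = flags)
}

#' Locate Q-band absorption peaks
#'
#' Finds the strongest strict local maxima of a molar absorption spectrum
#' inside a search window (default 500-600 nm, where hemoglobin shows its
#' two Q-band peaks near 545 and 579 nm). Peaks must be separated by at
#' least `min_separation_nm` (default 10 nm; the two Q-bands are ~34 nm
#' apart); ties break toward the lower wavelength. If fewer maxima exist
#' than requested, a shorter report is returned with a warning.
#'
#' @param eps A `molar_absorption` spectrum.
#' @param window Length-2 numeric search window in nm.
#' @param n_peaks Number of peaks to report (default 2).
#' @param min_separation_nm Minimum distance between reported peaks.
#' @return A `peak_report`: a data frame with columns `wavelength_nm` and
#'   `epsilon`, ordered by wavelength.
#' @export
find_q_band_peaks <- function(eps, window = c(500, 600), n_peaks = 2,
                              min_separation_nm = 10) {
  assert_kind(eps, "molar_absorption")
  if (window[1L] >= window[2L]) stop("window must satisfy lo < hi", call. = FALSE)
  keep <- eps$wavelength >= window[1L] & eps$wavelength <= window[2L]
  if (sum(keep) < 3L)
    stop("window must contain at least 3 spectrum samples", call. = FALSE)
  w <- eps$wavelength[keep]
  v <- eps$value[keep]
  n <- length(v)
  i <- 2:(n - 1)
  is_max <- v[i] > v[i - 1] & v[i] > v[i + 1]
  cand <- i[is_max]
  # strongest first; ties toward the lower wavelength
  cand <- cand[order(-v[cand], w[cand])]
  sel <- integer()
  for (j in cand) {
    if (length(sel) >= n_peaks) break
    if (all(abs(w[j] - w[sel]) >= min_separation_nm)) sel <- c(sel, j)
  }
  if (length(sel) < n_peaks)
    warning(sprintf("found %d local maxima in [%g, %g] nm, fewer than the %d requested",
                    length(sel), window[1L], window[2L], n_peaks), call. = FALSE)
  sel <- sel[order(w[sel])]
  structure(data.frame(wavelength_nm = w[sel], epsilon = v[sel]),
            class = c("peak_report", "data.frame"))
}

#' @export
print.peak_report <- function(x, ...) {
  if (!nrow(x)) {
    cat("<peak_report> no peaks\n")
    return(invisible(x))
  }
  cat("<peak_report>\n")
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %g nm: %.1f M^-1 cm^-1\n", x$wavelength_nm[i], x$epsilon[i]))
  invisible(x)
}

#' Experimental route: glycated-hemoglobin molar absorption spectrum
#'
#' End-to-end concentration-series estimation: replicate spectra are
#' averaged per concentration (in absorbance, where Beer-Lambert is
#' linear), the solution coefficient is fitted through the origin across
#' the series, the non-glycated contribution is removed using the
#' glycated fraction, the result is restricted to the reporting band, and
#' the Q-band peaks are located.
#'
#' @param replicates A single [concentration_series()] or a list of them
#'   (one per replicate measurement) sharing the design.
#' @param eps_non Non-glycated hemoglobin molar absorption spectrum; it
#'   is resampled onto the series grid, so its span must cover the band.
#' @param f Glycated molar fraction; defaults to the series' own value.
#' @param band Reporting band in nm (default 450-700).
#' @param window Peak search window in nm (default 500-600).
#' @return A list of class `experimental_fit` with elements `epsilon`
#'   (the band-restricted `molar_absorption` spectrum), `peaks` (a
#'   `peak_report`), and `eps_solution` (the uncorrected solution
#'   spectrum on the full grid).
#' @export
run_experimental_pipeline <- function(replicates, eps_non, f = NULL,
                                      band = c(450, 700),
                                      window = c(500, 600)) {
  if (inherits(replicates, "concentration_series")) replicates <- list(replicates)
  if (!length(replicates) ||
      !all(vapply(replicates, inherits, logical(1), "concentration_series")))
    stop("replicates must be one or more concentration_series", call. = FALSE)
  first <- replicates[[1L]]
  for (r in replicates[-1L]) {
    if (length(r$c_total) != length(first$c_total) ||
        any(r$c_total != first$c_total) ||
        r$path_length != first$path_length ||
        r$glycated_fraction != first$glycated_fraction)
      stop("replicate series must share concentrations, path length and glycated fraction",
           call. = FALSE)
  }
  f <- f %||% first$glycated_fraction
  averaged <- lapply(seq_along(first$c_total), function(i)
    average_replicates(lapply(replicates, function(r) r$spectra[[i]])))
  mean_series <- concentration_series(averaged, first$c_total,
                                      first$glycated_fraction,
                                      first$path_length, first$labels)
  eps_sol <- epsilon_solution_from_series(mean_series)
  eps_non_g <- resample_spectrum(eps_non, eps_sol$wavelength)
  eps_a1c <- correct_for_nonglycated(eps_sol, eps_non_g, f)
  eps_band <- restrict_band(eps_a1c, band[1L], band[2L])
  peaks <- find_q_band_peaks(eps_band, window = window)
  structure(list(epsilon = eps_band, peaks = peaks, eps_solution = eps_sol),
            class = "experimental_fit")
}

#' @export
print.experimental_fit <- function(x, ...) {
  cat("<experimental_fit>\n epsilon: ")
  print(x$epsilon)
  print(x$peaks)
  invisible(x)
}
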