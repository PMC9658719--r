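#' Construct a wavelength-indexed spectrum
#'
#' A spectrum is a set of (wavelength, value) samples of a declared kind:
#' percent transmittance (`%T`, dimensionless, in (0, 100]), absorbance
#' (`A`, dimensionless, unbounded above), or molar absorption coefficient
#' (M^-1 cm^-1). Wavelengths are in nanometres and must be strictly
#' increasing. Radiant intensities are never represented individually;
#' only their ratio enters through `%T = 100 * I/I0`.
#'
#' @param wavelength Numeric vector of wavelengths in nm; strictly
#'   increasing, finite, all positive, length >= 2.
#' @param value Numeric vector of the same length; finite. For
#'   `kind = "percent_transmittance"` values must lie in (0, 100]
#'   (zero excluded so absorbance stays finite).
#' @param kind One of `"percent_transmittance"`, `"absorbance"`,
#'   `"molar_absorption"`.
#' @param sd Optional per-wavelength dispersion (same length), attached by
#'   [average_replicates()].
#' @param flags Character vector of data-quality flags (e.g.
#'   `"negative_values"` on difference spectra).
#'
#' @return An object of class `hb_spectrum`: a list with elements
#'   `wavelength`, `value`, `kind`, and optionally `sd`, plus a `flags`
#'   attribute.
#' @examples
#' s <- hb_spectrum(450:700, rep(50, 251), "percent_transmittance")
#' transmittance_to_absorbance(s)
#' @export
hb_spectrum <- function(wavelength, value, kind = c("percent_transmittance",
                                                    "absorbance",
                                                    "molar_absorption"),
                        sd = NULL, flags = character()) {
  kind <- match.arg(kind)
  wavelength <- as.numeric(wavelength)
  value <- as.numeric(value)
  if (length(wavelength) != length(value))
    stop("wavelength and value must have the same length", call. = FALSE)
  if (length(wavelength) < 2L)
    stop("a spectrum needs at least 2 samples", call. = FALSE)
  if (!all(is.finite(wavelength)) || any(wavelength <= 0))
    stop("wavelengths must be finite and positive", call. = FALSE)
  if (any(diff(wavelength) <= 0))
    stop("wavelengths must be strictly increasing", call. = FALSE)
  if (!all(is.finite(value)))
    stop("spectrum values must be finite", call. = FALSE)
  if (kind == "percent_transmittance") {
    bad <- which(value <= 0 | value > 100)
    if (length(bad))
      stop(sprintf("percent transmittance must lie in (0, 100]; violated at %g nm",
                   wavelength[bad[1L]]), call. = FALSE)
  }
  if (!is.null(sd)) {
    sd <- as.numeric(sd)
    if (length(sd) != length(value) || any(!is.finite(sd)) || any(sd < 0))
      stop("sd must be a nonnegative numeric vector matching value", call. = FALSE)
  }
  structure(list(wavelength = wavelength, value = value, kind = kind, sd = sd),
            flags = unique(as.character(flags)),
            class = "hb_spectrum")
}

#' @export
print.hb_spectrum <- function(x, ...) {
  units <- switch(x$kind,
                  percent_transmittance = "%",
                  absorbance = "AU",
                  molar_absorption = "M^-1 cm^-1")
  cat(sprintf("<hb_spectrum> %s, %d samples, %.6g-%.6g nm\n",
              x$kind, length(x$wavelength),
              min(x$wavelength), max(x$wavelength)))
  cat(sprintf("  values [%s]: %.6g .. %.6g\n", units,
              min(x$value), max(x$value)))
  fl <- attr(x, "flags")
  if (length(fl)) cat("  flags:", paste(fl, collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.hb_spectrum <- function(x, ...) {
  d <- data.frame(wavelength_nm = x$wavelength, value = x$value)
  if (!is.null(x$sd)) d$sd <- x$sd
  d
}

spectrum_flags <- function(s) attr(s, "flags") %||% character()

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_kind <- function(s, kind) {
  if (!inherits(s, "hb_spectrum"))
    stop("expected an hb_spectrum object", call. = FALSE)
  if (s$kind != kind)
    stop(sprintf("expected a %s spectrum, got %s", kind, s$kind), call. = FALSE)
  invisible(s)
}

assert_same_grid <- function(a, b) {
  if (length(a$wavelength) != length(b$wavelength) ||
      any(a$wavelength != b$wavelength))
    stop("spectra are on different wavelength grids; resample first with resample_spectrum()",
         call. = FALSE)
  invisible(NULL)
}

#' Regular wavelength grid
#'
#' Generates a strictly increasing grid covering `[start_nm, stop_nm]`
#' inclusive to within one step. Used to align sample, solvent, and
#' reference spectra before pointwise arithmetic.
#'
#' @param start_nm,stop_nm Band limits in nm, `start_nm < stop_nm`, positive.
#' @param step_nm Grid spacing in nm, positive. Default 1 nm, the
#'   package's fixture convention.
#' @return An object of class `wavelength_grid` with fields `start_nm`,
#'   `stop_nm`, `step_nm`, `wavelength`.
#' @examples
#' wavelength_grid(450, 700)
#' @export
wavelength_grid <- function(start_nm, stop_nm, step_nm = 1) {
  if (!is.finite(start_nm) || !is.finite(stop_nm) || !is.finite(step_nm) ||
      start_nm <= 0 || step_nm <= 0 || start_nm >= stop_nm)
    stop("need 0 < start_nm < stop_nm and step_nm > 0", call. = FALSE)
  structure(list(start_nm = start_nm, stop_nm = stop_nm, step_nm = step_nm,
                 wavelength = seq(start_nm, stop_nm, by = step_nm)),
            class = "wavelength_grid")
}

#' @export
print.wavelength_grid <- function(x, ...) {
  cat(sprintf("<wavelength_grid> %g-%g nm, step %g nm (%d points)\n",
              x$start_nm, x$stop_nm, x$step_nm, length(x$wavelength)))
  invisible(x)
}

grid_points <- function(g) {
  if (inherits(g, "wavelength_grid")) g$wavelength else as.numeric(g)
}

#' Convert percent transmittance to absorbance
#'
#' Pointwise `A = 2 - log10(%T)`, the common-log Beer-Lambert relation
#' (equivalently `A = -log10(T)` with `T = %T/100`). Base-10 logarithms
#' are used throughout the package; the `2 - log10(%T)` form only holds
#' in base 10.
#'
#' @param s A percent-transmittance spectrum with values in (0, 100].
#' @return An absorbance spectrum on the same grid; all values >= 0.
#' @examples
#' s <- hb_spectrum(c(500, 600), c(10, 50), "percent_transmittance")
#' transmittance_to_absorbance(s)$value  # 1, 0.30103
#' @export
transmittance_to_absorbance <- function(s) {
  assert_kind(s, "percent_transmittance")
  hb_spectrum(s$wavelength, 2 - log10(s$value), "absorbance")
}

#' Convert absorbance to percent transmittance
#'
#' Pointwise `%T = 100 * 10^(-A)`. Negative absorbance corresponds to
#' `%T > 100`, which is unphysical for a raw measurement; it is rejected
#' unless `allow_negative = TRUE` (useful for difference spectra that dip
#' slightly below zero under noise), in which case the result carries a
#' `"transmittance_above_100"` flag. Round trip with
#' [transmittance_to_absorbance()] is identity within 1e-12 relative.
#'
#' @param s An absorbance spectrum.
#' @param allow_negative Permit negative absorbance values.
#' @return A spectrum of kind `percent_transmittance` (values capped only
#'   by the (0, 100] invariant when `allow_negative = FALSE`).
#' @export
absorbance_to_transmittance <- function(s, allow_negative = FALSE) {
  assert_kind(s, "absorbance")
  if (any(s$value < 0)) {
    if (!allow_negative) {
      bad <- which(s$value < 0)[1L]
      stop(sprintf("negative absorbance at %g nm implies %%T > 100; set allow_negative = TRUE to permit",
                   s$wavelength[bad]), call. = FALSE)
    }
    pct <- 100 * 10^(-s$value)
    # bypass the (0, 100] invariant deliberately: flagged difference spectrum
    out <- hb_spectrum(s$wavelength, pmin(pct, 100), "percent_transmittance")
    out$value <- pct
    attr(out, "flags") <- union(spectrum_flags(out), "transmittance_above_100")
    return(out)
  }
  hb_spectrum(s$wavelength, 100 * 10^(-s$value), "percent_transmittance")
}

#' Resample a spectrum onto a wavelength grid
#'
#' Linear interpolation onto the target grid; the only grid-alignment
#' path in the package, so that all pointwise operations agree on how
#' interpolation is done. Extrapolation is refused: the grid must lie
#' inside the wavelength span of `s`. Grid points coinciding with input
#' wavelengths reproduce the stored values exactly.
#'
#' @param s A spectrum of any kind.
#' @param grid A [wavelength_grid()] or numeric vector of target
#'   wavelengths (nm), strictly increasing.
#' @return A spectrum of the same kind on the target grid (any attached
#'   `sd` is dropped).
#' @export
resample_spectrum <- function(s, grid) {
  if (!inherits(s, "hb_spectrum")) stop("s must be an hb_spectrum", call. = FALSE)
  xout <- grid_points(grid)
  lo <- min(s$wavelength); hi <- max(s$wavelength)
  if (min(xout) < lo || max(xout) > hi)
    stop(sprintf("grid [%g, %g] nm extends outside the spectrum span [%g, %g] nm; no extrapolation",
                 min(xout), max(xout), lo, hi), call. = FALSE)
  v <- stats::approx(s$wavelength, s$value, xout = xout, method = "linear",
                     ties = "ordered")$y
  hb_spectrum(xout, v, s$kind, flags = spectrum_flags(s))
}

#' Interpolated spectrum value at arbitrary wavelengths
#'
#' @param s A spectrum.
#' @param wavelength_nm Numeric vector inside the spectrum span.
#' @return Numeric vector of linearly interpolated values.
#' @keywords internal
interp_value <- function(s, wavelength_nm) {
  lo <- min(s$wavelength); hi <- max(s$wavelength)
  if (any(wavelength_nm < lo | wavelength_nm > hi))
    stop(sprintf("requested wavelength outside spectrum span [%g, %g] nm", lo, hi),
         call. = FALSE)
  stats::approx(s$wavelength, s$value, xout = wavelength_nm,
                method = "linear", ties = "ordered")$y
}

#' Subtract one absorbance spectrum from another
#'
#' Pointwise `minuend - subtrahend`, the solvent-subtraction step that
#' isolates the solute contribution from the solution spectrum
#' (`A_solute = A_solution - A_solvent`). Both spectra must be on the
#' same grid; resample first. Negative differences are preserved (they
#' arise legitimately under noise) and flagged `"negative_values"`.
#'
#' @param minuend,subtrahend Absorbance spectra on identical grids.
#' @return The difference absorbance spectrum.
#' @export
subtract_absorbance <- function(minuend, subtrahend) {
  assert_kind(minuend, "absorbance")
  assert_kind(subtrahend, "absorbance")
  assert_same_grid(minuend, subtrahend)
  v <- minuend$value - subtrahend$value
  flags <- if (any(v < 0)) "negative_values" else character()
  hb_spectrum(minuend$wavelength, v, "absorbance", flags = flags)
}

#' Average replicate spectra
#'
#' Pointwise arithmetic mean with the sample standard deviation (n - 1
#' denominator; zero when n = 1) attached as `sd`. Averaging is done in
#' whatever domain the replicates are in; the recommended convention is
#' to average absorbance, where the Beer-Lambert law is linear.
#'
#' @param replicates A list of >= 1 spectra with identical grids and kinds.
#' @return A spectrum of the shared kind with per-wavelength `sd`.
#' @export
average_replicates <- function(replicates) {
  if (!is.list(replicates) || length(replicates) < 1L)
    stop("replicates must be a non-empty list of spectra", call. = FALSE)
  lapply(replicates, function(s) {
    if (!inherits(s, "hb_spectrum")) stop("replicates must be hb_spectrum objects", call. = FALSE)
  })
  first <- replicates[[1L]]
  for (s in replicates[-1L]) {
    if (s$kind != first$kind)
      stop("replicates have mixed kinds", call. = FALSE)
    assert_same_grid(first, s)
  }
  vals <- vapply(replicates, `[[`, numeric(length(first$value)), "value")
  vals <- matrix(vals, nrow = length(first$value))
  m <- rowMeans(vals)
  n <- ncol(vals)
  s2 <- if (n > 1L) rowSums((vals - m)^2) / (n - 1) else rep(0, length(m))
  hb_spectrum(first$wavelength, m, first$kind, sd = sqrt(s2))
}

#' Restrict a spectrum to a wavelength band
#'
#' Keeps samples with `lo_nm <= wavelength <= hi_nm`, e.g. the 450-700 nm
#' visible band in which hemoglobin molar absorption spectra are reported.
#'
#' @param s A spectrum.
#' @param lo_nm,hi_nm Band limits, `lo_nm < hi_nm`.
#' @return The band-restricted spectrum (at least 2 samples must remain).
#' @export
restrict_band <- function(s, lo_nm, hi_nm) {
  if (!inherits(s, "hb_spectrum")) stop("s must be an hb_spectrum", call. = FALSE)
  if (!is.finite(lo_nm) || !is.finite(hi_nm) || lo_nm >= hi_nm)
    stop("need lo_nm < hi_nm", call. = FALSE)
  keep <- s$wavelength >= lo_nm & s$wavelength <= hi_nm
  if (!any(keep))
    stop(sprintf("band [%g, %g] nm does not intersect the spectrum", lo_nm, hi_nm),
         call. = FALSE)
  hb_spectrum(s$wavelength[keep], s$value[keep], s$kind,
              sd = if (!is.null(s$sd)) s$sd[keep],
              flags = spectrum_flags(s))
}
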