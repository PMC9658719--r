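#' Literature reference anchor for absolute scaling
#'
#' A known molar absorption coefficient at one wavelength, used to rescale
#' a relative (arbitrarily normalized) absorbance spectrum to absolute
#' M^-1 cm^-1 units. Typical anchors for glycated hemoglobin are the
#' literature values at 535 nm and 593 nm.
#'
#' @param wavelength_nm Anchor wavelength in nm (> 0).
#' @param epsilon Molar absorption coefficient at that wavelength,
#'   M^-1 cm^-1 (> 0).
#' @return An object of class `reference_anchor`.
#' @examples
#' reference_anchor(535, 710888)
#' @export
reference_anchor <- function(wavelength_nm, epsilon) {
  if (!is.finite(wavelength_nm) || wavelength_nm <= 0)
    stop("anchor wavelength must be positive and finite", call. = FALSE)
  if (!is.finite(epsilon) || epsilon <= 0)
    stop("anchor epsilon must be positive and finite", call. = FALSE)
  structure(list(wavelength_nm = wavelength_nm, epsilon = epsilon),
            class = "reference_anchor")
}

#' @export
print.reference_anchor <- function(x, ...) {
  cat(sprintf("<reference_anchor> %g nm: %.1f M^-1 cm^-1\n",
              x$wavelength_nm, x$epsilon))
  invisible(x)
}

as_anchor_list <- function(anchors) {
  if (inherits(anchors, "reference_anchor")) anchors <- list(anchors)
  if (!is.list(anchors) || !length(anchors) ||
      !all(vapply(anchors, inherits, logical(1), "reference_anchor")))
    stop("anchors must be a reference_anchor or a non-empty list of them",
         call. = FALSE)
  anchors
}

#' Component absorbance by solvent subtraction
#'
#' Converts solution and solvent percent-transmittance spectra to
#' absorbance (`A = 2 - log10(%T)`) and subtracts the solvent, isolating
#' the absorbance attributable to the dissolved hemoglobin:
#' `A_component = A_solution - A_solvent`.
#'
#' @param sol_T Percent-transmittance spectrum of the solution.
#' @param solvent_T Percent-transmittance spectrum of the solvent (same grid).
#' @return The component absorbance spectrum (differences may be negative
#'   under noise and are flagged, not clipped).
#' @export
component_absorbance <- function(sol_T, solvent_T) {
  subtract_absorbance(transmittance_to_absorbance(sol_T),
                      transmittance_to_absorbance(solvent_T))
}

#' Scale factor mapping a relative spectrum to an anchor
#'
#' For a relative absorbance spectrum whose overall normalization is
#' unknown (the measured absorbance is only proportional to the molar
#' absorption coefficient, with an unidentified factor absorbing the
#' normalization, the concentration and the path length), the scale that
#' makes the spectrum match a literature anchor is
#' `scale = epsilon_anchor / rel(lambda_anchor)`. The anchor value is
#' read off the spectrum by the same linear interpolation used by
#' [resample_spectrum()].
#'
#' @param rel Relative absorbance spectrum.
#' @param anchor A [reference_anchor()] whose wavelength lies in the span
#'   of `rel`.
#' @return The scale in M^-1 cm^-1 per absorbance unit.
#' @export
anchor_scale_factor <- function(rel, anchor) {
  assert_kind(rel, "absorbance")
  if (!inherits(anchor, "reference_anchor"))
    stop("anchor must be a reference_anchor", call. = FALSE)
  a <- interp_value(rel, anchor$wavelength_nm)
  if (!is.finite(a) || a <= 0)
    stop(sprintf("relative absorbance at anchor wavelength %g nm is %g; anchor is degenerate",
                 anchor$wavelength_nm, a), call. = FALSE)
  anchor$epsilon / a
}

#' Rescale a relative absorbance spectrum to molar absorption units
#'
#' Multiplies the relative spectrum by an anchor-derived scale. Because
#' the scale is a ratio, the output is invariant to any positive
#' rescaling of the input: an unknown normalization factor in the
#' transmittance-derived absorbance cancels exactly. With one anchor the
#' output passes through the anchor value; with several, per-anchor
#' scales are combined by their geometric mean (scale factors compose
#' multiplicatively). Per-anchor scales disagreeing by more than 1% are
#' reported as a data-quality warning, since consistent data must give
#' identical scales at every anchor.
#'
#' @param rel Relative absorbance spectrum (values at the anchor
#'   wavelengths must be positive; negative values elsewhere are scaled
#'   through and flagged, not clipped).
#' @param anchors A [reference_anchor()] or list of them.
#' @param policy `"single"` uses the first anchor's scale;
#'   `"geometric_mean"` (default) combines all anchors.
#' @return A spectrum of kind `molar_absorption` on the grid of `rel`.
#' @export
scale_spectrum_to_anchors <- function(rel, anchors,
                                      policy = c("geometric_mean", "single")) {
  policy <- match.arg(policy)
  anchors <- as_anchor_list(anchors)
  scales <- vapply(anchors, function(a) anchor_scale_factor(rel, a), numeric(1))
  if (length(scales) > 1L && max(scales) / min(scales) > 1.01)
    warning(sprintf("per-anchor scales differ by %.2f%% (> 1%%): anchors are inconsistent with the spectrum shape",
                    100 * (max(scales) / min(scales) - 1)), call. = FALSE)
  s <- if (policy == "single") scales[1L] else exp(mean(log(scales)))
  v <- rel$value * s
  flags <- if (any(v < 0)) "negative_values" else character()
  out <- hb_spectrum(rel$wavelength, v, "molar_absorption", flags = flags)
  attr(out, "anchor_scales") <- scales
  out
}

#' Theoretical route: anchored molar absorption spectrum
#'
#' End-to-end reference-anchored estimation: solvent subtraction of the
#' transmittance-derived absorbance, restriction to the reporting band,
#' and anchor rescaling to absolute units. The result is independent of
#' any positive normalization applied to the input absorbance, which is
#' what makes the method usable on normalized published transmittance
#' curves.
#'
#' @param sol_T,solvent_T Percent-transmittance spectra on a common grid.
#' @param anchors A [reference_anchor()] or list of them.
#' @param band Length-2 numeric, reporting band in nm (default 450-700).
#' @param policy Anchor combination policy, see
#'   [scale_spectrum_to_anchors()].
#' @return Molar absorption spectrum over the band.
#' @examples
#' grid <- wavelength_grid(450, 700)
#' truth <- gaussian_band_spectrum(hb_band_preset("level1"), grid)
#' A <- hb_spectrum(truth$wavelength, truth$value * 5e-5, "absorbance")
#' sol <- absorbance_to_transmittance(A)
#' solv <- hb_spectrum(truth$wavelength, rep(100, 251), "percent_transmittance")
#' anc <- reference_anchor(535, truth$value[truth$wavelength == 535])
#' eps <- run_theoretical_pipeline(sol, solv, anc)
#' @export
run_theoretical_pipeline <- function(sol_T, solvent_T, anchors,
                                     band = c(450, 700),
                                     policy = c("geometric_mean", "single")) {
  rel <- component_absorbance(sol_T, solvent_T)
  rel <- restrict_band(rel, band[1L], band[2L])
  scale_spectrum_to_anchors(rel, anchors, match.arg(policy))
}
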