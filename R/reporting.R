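#' Look up molar absorption coefficients at specific wavelengths
#'
#' Linear interpolation of a molar absorption spectrum at requested
#' wavelengths — the operation behind wavelength-specific comparison
#' tables (e.g. values at 535 and 593 nm, or at an LED triplet). Values
#' are stored at full precision; the print method shows one decimal in
#' M^-1 cm^-1.
#'
#' @param eps A `molar_absorption` spectrum.
#' @param wavelengths_nm Numeric vector inside the spectrum span.
#' @return A data frame (class `epsilon_lookup`) with columns
#'   `wavelength_nm` and `epsilon`.
#' @export
lookup_epsilon <- function(eps, wavelengths_nm) {
  assert_kind(eps, "molar_absorption")
  structure(data.frame(wavelength_nm = as.numeric(wavelengths_nm),
                       epsilon = interp_value(eps, wavelengths_nm)),
            class = c("epsilon_lookup", "data.frame"))
}

#' @export
print.epsilon_lookup <- function(x, ...) {
  cat("<epsilon_lookup>\n")
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %g nm: %.1f M^-1 cm^-1\n", x$wavelength_nm[i], x$epsilon[i]))
  invisible(x)
}

#' Compare two molar absorption spectra at chosen wavelengths
#'
#' Builds a row-per-wavelength comparison between two estimates of the
#' same spectrum (e.g. anchor-scaled vs. concentration-series routes)
#' with the symmetric relative difference `|e1 - e2| / max(e1, e2)`.
#' Maximum and mean relative differences are attached as a summary.
#'
#' @param e1,e2 `molar_absorption` spectra whose spans cover
#'   `wavelengths_nm`.
#' @param wavelengths_nm Wavelengths at which to compare.
#' @return A data frame (class `comparison_table`) with columns
#'   `wavelength_nm`, `epsilon_1`, `epsilon_2`, `relative_difference`,
#'   and attribute `summary` (named vector `max`, `mean`).
#' @export
compare_spectra <- function(e1, e2, wavelengths_nm) {
  v1 <- lookup_epsilon(e1, wavelengths_nm)$epsilon
  v2 <- lookup_epsilon(e2, wavelengths_nm)$epsilon
  rel <- abs(v1 - v2) / pmax(v1, v2)
  out <- data.frame(wavelength_nm = as.numeric(wavelengths_nm),
                    epsilon_1 = v1, epsilon_2 = v2,
                    relative_difference = rel)
  attr(out, "summary") <- c(max = max(rel), mean = mean(rel))
  class(out) <- c("comparison_table", "data.frame")
  out
}

#' @export
print.comparison_table <- function(x, ...) {
  cat("<comparison_table>\n")
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %g nm: %.1f vs %.1f (rel. diff %.3g)\n",
                x$wavelength_nm[i], x$epsilon_1[i], x$epsilon_2[i],
                x$relative_difference[i]))
  s <- attr(x, "summary")
  cat(sprintf("  max rel. diff %.3g, mean %.3g\n", s[["max"]], s[["mean"]]))
  invisible(x)
}

#' Write a JSON run manifest
#'
#' Records what a run consumed and produced: a config echo, MD5
#' checksums of the input files, the package version, the seed, and a
#' timestamp — enough to re-run and compare. Two runs with identical
#' config and seed produce manifests identical except for the timestamp.
#'
#' @param config Named list describing the run (band, window, anchors,
#'   fraction source, ...); `config$seed` is echoed into the top-level
#'   `seed` field.
#' @param inputs Character vector of input file paths (checksummed).
#' @param outputs Character vector of output file paths (listed).
#' @param path Destination of the manifest JSON.
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(config, inputs = character(),
                           outputs = character(), path) {
  checksums <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  manifest <- list(
    package = "hba1cspec",
    version = as.character(utils::packageVersion("hba1cspec")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    config = config,
    input_checksums = checksums,
    outputs = as.list(outputs)
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(manifest)
}

#' Path to the synthetic non-glycated hemoglobin reference spectrum
#'
#' The experimental correction needs a molar absorption table for
#' non-glycated hemoglobin; real analyses should supply a literature
#' table. The packaged file is a synthetic stand-in generated by
#' [gaussian_band_spectrum()] with the `"nonglycated"` preset
#' (oxyhemoglobin-like Q-bands on a declining baseline), suitable for
#' examples and pipeline tests only.
#'
#' @return File path of the packaged CSV.
#' @examples
#' eps_non <- read_spectrum(eps_non_fixture_path())
#' @export
eps_non_fixture_path <- function() {
  system.file("extdata", "eps_nonglycated_synthetic.csv",
              package = "hba1cspec", mustWork = TRUE)
}
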