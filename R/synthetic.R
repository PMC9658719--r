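#' Gaussian band model for hemoglobin-like spectra
#'
#' Parameterizes a molar absorption spectrum as a sum of Gaussian bands
#' plus an optional exponentially declining baseline. Gaussian shapes are
#' a computational stand-in for peak-recovery testing, not a claim about
#' hemoglobin photophysics.
#'
#' @param centers_nm Band centers in nm, each within 300-1100.
#' @param widths_nm Gaussian standard deviations in nm (> 0), recycled.
#' @param amplitudes Peak molar absorption amplitudes in M^-1 cm^-1
#'   (>= 0), recycled.
#' @param baseline_amplitude Baseline value at 300 nm, M^-1 cm^-1 (>= 0).
#' @param baseline_decay_nm e-folding length of the declining baseline
#'   (> 0).
#' @return An object of class `band_model`.
#' @export
band_model <- function(centers_nm, widths_nm, amplitudes,
                       baseline_amplitude = 0, baseline_decay_nm = 150) {
  n <- length(centers_nm)
  widths_nm <- rep_len(widths_nm, n)
  amplitudes <- rep_len(amplitudes, n)
  if (n && (any(centers_nm < 300) || any(centers_nm > 1100)))
    stop("band centers must lie within 300-1100 nm", call. = FALSE)
  if (any(widths_nm <= 0)) stop("band widths must be positive", call. = FALSE)
  if (any(amplitudes < 0)) stop("band amplitudes must be nonnegative", call. = FALSE)
  if (baseline_amplitude < 0 || baseline_decay_nm <= 0)
    stop("baseline amplitude must be >= 0 and decay > 0", call. = FALSE)
  structure(list(centers_nm = centers_nm, widths_nm = widths_nm,
                 amplitudes = amplitudes,
                 baseline_amplitude = baseline_amplitude,
                 baseline_decay_nm = baseline_decay_nm),
            class = "band_model")
}

#' Preset band models for the bilevel control material
#'
#' Q-band centers follow the observed peak positions of the two control
#' levels (545/579 nm for level 1, 544/577 nm for level 2); amplitudes
#' are fixture choices placing the peak molar absorption in the
#' 4e5-9e5 M^-1 cm^-1 range typical of hemoglobin Q-bands. The
#' `"nonglycated"` preset is a synthetic oxyhemoglobin-like reference
#' spectrum used where a literature non-glycated-hemoglobin table would
#' stand in real use.
#'
#' @param preset `"level1"`, `"level2"`, or `"nonglycated"`.
#' @return A [band_model()].
#' @examples
#' gaussian_band_spectrum(hb_band_preset("level1"), wavelength_grid(450, 700))
#' @export
hb_band_preset <- function(preset = c("level1", "level2", "nonglycated")) {
  preset <- match.arg(preset)
  switch(preset,
         level1 = band_model(c(545, 579), c(10, 10), c(8.0e5, 7.0e5),
                             baseline_amplitude = 1.2e5,
                             baseline_decay_nm = 150),
         level2 = band_model(c(544, 577), c(10, 10), c(5.0e5, 4.7e5),
                             baseline_amplitude = 1.0e5,
                             baseline_decay_nm = 150),
         nonglycated = band_model(c(541, 576), c(11, 10), c(5.5e5, 5.0e5),
                                  baseline_amplitude = 3e5,
                                  baseline_decay_nm = 120))
}

#' Evaluate a band model on a wavelength grid
#'
#' `eps(lambda) = sum_j a_j * exp(-(lambda - c_j)^2 / (2 w_j^2)) +
#' b * exp(-(lambda - 300)/tau)`; nonnegative by construction.
#'
#' @param model A [band_model()].
#' @param grid A [wavelength_grid()] or numeric wavelength vector (nm).
#' @return A `molar_absorption` spectrum.
#' @export
gaussian_band_spectrum <- function(model, grid) {
  if (!inherits(model, "band_model"))
    stop("model must be a band_model", call. = FALSE)
  w <- grid_points(grid)
  v <- rep(0, length(w))
  for (j in seq_along(model$centers_nm))
    v <- v + model$amplitudes[j] *
      exp(-(w - model$centers_nm[j])^2 / (2 * model$widths_nm[j]^2))
  if (model$baseline_amplitude > 0)
    v <- v + model$baseline_amplitude *
      exp(-(w - 300) / model$baseline_decay_nm)
  hb_spectrum(w, v, "molar_absorption")
}

#' Simulate a replicated concentration-series measurement
#'
#' Forward Beer-Lambert model of the dilution-series experiment: for each
#' concentration `c` the mixture absorbance is
#' `A(lambda) = (f * eps_a1c + (1 - f) * eps_non) * c * d + noise`, with
#' independent additive Gaussian noise (absorbance domain) per replicate.
#' Matching percent-transmittance spectra are produced as
#' `%T = 100 * 10^(-k * A)`, where the normalization factor `k`
#' multiplies the absorbance — the arbitrary positive rescaling that the
#' anchor-based theoretical route must cancel. All stochastic draws come
#' from one seeded stream, so identical seeds give identical outputs.
#'
#' @param eps_a1c,eps_non Ground-truth `molar_absorption` spectra of the
#'   glycated and non-glycated components, identical grids.
#' @param glycated_fraction Molar fraction `f` in (0, 1].
#' @param concentrations Total hemoglobin concentrations in mol/L;
#'   default is the study's dilution series 0.07, 0.06, 0.05, 0.04,
#'   0.03 mmol/L.
#' @param path_length Cuvette path length in cm (default 1).
#' @param noise_sd Additive absorbance noise standard deviation
#'   (default 0, noiseless).
#' @param replicates Number of replicate measurements (default 3, each
#'   cuvette measured three times).
#' @param normalization_k Positive factor multiplying the absorbance in
#'   the emitted transmittance spectra (default 1, unnormalized).
#' @param seed Optional integer seed.
#' @return A list of class `simulated_series`: `replicates` (list of
#'   [concentration_series()], one per replicate), `transmittance`
#'   (parallel list of lists of `%T` spectra), and `truth` (the
#'   generating parameters, for recovery tests).
#' @export
simulate_measurement_series <- function(eps_a1c, eps_non, glycated_fraction,
                                        concentrations = c(7, 6, 5, 4, 3) * 1e-5,
                                        path_length = 1,
                                        noise_sd = 0, replicates = 3,
                                        normalization_k = 1, seed = NULL) {
  assert_kind(eps_a1c, "molar_absorption")
  assert_kind(eps_non, "molar_absorption")
  assert_same_grid(eps_a1c, eps_non)
  if (!is.finite(glycated_fraction) || glycated_fraction <= 0 ||
      glycated_fraction > 1)
    stop("glycated_fraction must lie in (0, 1]", call. = FALSE)
  if (any(concentrations <= 0) || anyDuplicated(concentrations))
    stop("concentrations must be positive and distinct", call. = FALSE)
  if (replicates < 1L) stop("need at least one replicate", call. = FALSE)
  if (!is.finite(noise_sd) || noise_sd < 0)
    stop("noise_sd must be nonnegative", call. = FALSE)
  if (!is.finite(normalization_k) || normalization_k <= 0)
    stop("normalization_k must be positive", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  w <- eps_a1c$wavelength
  eps_mix <- glycated_fraction * eps_a1c$value +
    (1 - glycated_fraction) * eps_non$value
  rep_series <- vector("list", replicates)
  rep_transmittance <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    spectra <- vector("list", length(concentrations))
    t_spectra <- vector("list", length(concentrations))
    for (i in seq_along(concentrations)) {
      A <- eps_mix * concentrations[i] * path_length
      if (noise_sd > 0) A <- A + stats::rnorm(length(w), sd = noise_sd)
      # noise may push A slightly negative; keep it, flagged
      spectra[[i]] <- hb_spectrum(w, A, "absorbance",
                                  flags = if (any(A < 0)) "negative_values")
      t_spectra[[i]] <- absorbance_to_transmittance(
        hb_spectrum(w, normalization_k * pmax(A, .Machine$double.xmin),
                    "absorbance"))
    }
    rep_series[[r]] <- concentration_series(spectra, concentrations,
                                            glycated_fraction, path_length)
    rep_transmittance[[r]] <- t_spectra
  }
  structure(list(replicates = rep_series,
                 transmittance = rep_transmittance,
                 truth = list(eps_a1c = eps_a1c, eps_non = eps_non,
                              glycated_fraction = glycated_fraction,
                              concentrations = concentrations,
                              path_length = path_length,
                              noise_sd = noise_sd,
                              normalization_k = normalization_k)),
            class = "simulated_series")
}

#' Simulate error-grid point clouds with prescribed zone counts
#'
#' Draws reference/estimate HbA1c pairs whose [assign_zone()] labels
#' match the requested per-zone counts exactly, by rejection sampling
#' inside each zone's region. Used to rebuild error-grid summaries from
#' published zone counts.
#'
#' @param n Total number of points; must equal `sum(zone_counts)`.
#' @param zone_counts Named integer vector with entries `A`, `B`, `C`.
#' @param policy A [zone_policy()].
#' @param seed Optional integer seed.
#' @param reference_range HbA1c range (NGSP %) from which references are
#'   drawn (default 4-12%).
#' @return A data frame with columns `reference`, `estimate`, `zone`.
#' @examples
#' pts <- simulate_ega_points(19, c(A = 14, B = 5, C = 0), seed = 1)
#' summarize_zones(pts$reference, pts$estimate)
#' @export
simulate_ega_points <- function(n, zone_counts, policy = zone_policy(),
                                seed = NULL, reference_range = c(4, 12)) {
  zone_counts <- zone_counts[c("A", "B", "C")]
  zone_counts[is.na(zone_counts)] <- 0L
  names(zone_counts) <- c("A", "B", "C")
  if (any(zone_counts < 0) || sum(zone_counts) != n)
    stop("zone_counts must be nonnegative and sum to n", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  draw_zone <- function(zone, count) {
    out <- matrix(numeric(), ncol = 2)
    tries <- 0L
    while (nrow(out) < count) {
      tries <- tries + 1L
      if (tries > 100000L)
        stop(sprintf("could not realize zone %s under this policy; infeasible mix",
                     zone), call. = FALSE)
      ref <- stats::runif(1, reference_range[1L], reference_range[2L])
      est <- switch(zone,
                    A = ref * (1 + stats::runif(1, -policy$zone_a_rel_tol,
                                                policy$zone_a_rel_tol)),
                    B = ref * (1 + sample(c(-1, 1), 1) *
                                 stats::runif(1, policy$zone_a_rel_tol + 0.01, 0.6)),
                    C = stats::runif(1, reference_range[1L], reference_range[2L]))
      if (est <= 0) next
      if (assign_zone(ref, est, policy) == zone)
        out <- rbind(out, c(ref, est))
    }
    out
  }
  pts <- do.call(rbind, lapply(names(zone_counts), function(z)
    draw_zone(z, zone_counts[[z]])))
  data.frame(reference = pts[, 1L], estimate = pts[, 2L],
             zone = assign_zone(pts[, 1L], pts[, 2L], policy))
}
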