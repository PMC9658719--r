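#' Zone policy for the three-zone error grid
#'
#' Parameters of the HbA1c error-grid classification: the relative
#' tolerance defining clinically accurate zone A, and the NGSP diagnostic
#' cutpoints used to decide when a misestimate crosses treatment
#' categories (zone C).
#'
#' @param zone_a_rel_tol Relative tolerance for zone A (default 0.20, the
#'   "within 20% of the reference" rule), in (0, 1); the boundary is
#'   inclusive.
#' @param normal_max Upper limit of the normal NGSP category (exclusive):
#'   values below 5.7% are normal.
#' @param diabetes_min Lower limit of the diabetes category (exclusive):
#'   values above 6.4% indicate diabetes; the prediabetes band
#'   5.7-6.4% is inclusive at both ends.
#' @return An object of class `zone_policy`.
#' @export
zone_policy <- function(zone_a_rel_tol = 0.20, normal_max = 5.7,
                        diabetes_min = 6.4) {
  if (!is.finite(zone_a_rel_tol) || zone_a_rel_tol <= 0 || zone_a_rel_tol >= 1)
    stop("zone_a_rel_tol must lie in (0, 1)", call. = FALSE)
  if (!is.finite(normal_max) || !is.finite(diabetes_min) ||
      normal_max >= diabetes_min)
    stop("category cutpoints must be finite and strictly increasing", call. = FALSE)
  structure(list(zone_a_rel_tol = zone_a_rel_tol, normal_max = normal_max,
                 diabetes_min = diabetes_min),
            class = "zone_policy")
}

#' NGSP diagnostic category of an HbA1c value
#'
#' Standard NGSP interpretation: below 5.7% normal, 5.7% to 6.4%
#' (inclusive) prediabetes, above 6.4% diabetes.
#'
#' @param value Numeric vector of HbA1c percentages (> 0, NGSP scale).
#' @param policy A [zone_policy()] carrying the cutpoints.
#' @return Character vector in `{"normal", "prediabetes", "diabetes"}`.
#' @examples
#' classify_ngsp(c(5.6, 6.4, 6.41))
#' @export
classify_ngsp <- function(value, policy = zone_policy()) {
  if (any(!is.finite(value)) || any(value <= 0))
    stop("HbA1c values must be positive and finite", call. = FALSE)
  ifelse(value < policy$normal_max, "normal",
         ifelse(value <= policy$diabetes_min, "prediabetes", "diabetes"))
}

#' Assign error-grid zones to reference/estimate pairs
#'
#' Three-zone classification of an estimated HbA1c value against its
#' reference: zone A when the estimate lies within the relative tolerance
#' of the reference (boundary inclusive); zone C when the estimate's
#' NGSP category implies treatment the reference's category does not (a
#' normal subject estimated diabetic, or a diabetic subject estimated
#' normal — both clinically dangerous crossings share the single C
#' bucket of a three-zone grid); zone B otherwise (outside tolerance but
#' not category-crossing). Assignment is exhaustive and exclusive.
#'
#' @param reference,estimate Positive numeric vectors of equal length,
#'   HbA1c % on the NGSP scale.
#' @param policy A [zone_policy()].
#' @return Character vector of zones `"A"`, `"B"`, `"C"`.
#' @examples
#' assign_zone(c(6, 10, 5, 8), c(6, 12, 7, 10))  # A A C B
#' @export
assign_zone <- function(reference, estimate, policy = zone_policy()) {
  if (length(reference) != length(estimate))
    stop("reference and estimate must have equal length", call. = FALSE)
  if (any(!is.finite(reference)) || any(reference <= 0) ||
      any(!is.finite(estimate)) || any(estimate <= 0))
    stop("reference and estimate must be positive and finite", call. = FALSE)
  in_a <- abs(estimate - reference) <= policy$zone_a_rel_tol * reference
  ref_cat <- classify_ngsp(reference, policy)
  est_cat <- classify_ngsp(estimate, policy)
  crossing <- (ref_cat == "normal" & est_cat == "diabetes") |
    (ref_cat == "diabetes" & est_cat == "normal")
  ifelse(in_a, "A", ifelse(crossing, "C", "B"))
}

round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Summarize error-grid zone membership
#'
#' Counts reference/estimate pairs per zone and reports percentages as
#' `100 * count / total`, rounded half-up to two decimals (so 14 of 19
#' points in zone A reports 73.68%).
#'
#' @param reference,estimate Positive numeric vectors (HbA1c %).
#' @param policy A [zone_policy()].
#' @return An object of class `ega_summary`: list with `counts` and
#'   `percentages` (named numeric vectors over zones A, B, C), `zones`
#'   (per-point labels), and `n`.
#' @export
summarize_zones <- function(reference, estimate, policy = zone_policy()) {
  if (!length(reference))
    stop("at least one reference/estimate pair is required", call. = FALSE)
  zones <- assign_zone(reference, estimate, policy)
  counts <- vapply(c(A = "A", B = "B", C = "C"),
                   function(z) sum(zones == z), integer(1))
  percentages <- round_half_up(100 * counts / length(zones), 2)
  structure(list(counts = counts, percentages = percentages,
                 zones = zones, n = length(zones)),
            class = "ega_summary")
}

#' @export
print.ega_summary <- function(x, ...) {
  cat(sprintf("<ega_summary> %d points\n", x$n))
  for (z in names(x$counts))
    cat(sprintf("  zone %s: %d (%.2f%%)\n", z, x$counts[[z]], x$percentages[[z]]))
  invisible(x)
}
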