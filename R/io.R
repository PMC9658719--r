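#' Read a spectrum from CSV/TSV
#'
#' The package's spectral file dialect: an optional leading comment line
#' `# kind: <kind>`, then a header `wavelength_nm,value` (comma or tab
#' separated) and one row per sample. Monotonicity and kind invariants are
#' validated on read.
#'
#' @param path File path.
#' @param kind Spectrum kind; overrides (and is required in the absence
#'   of) the `# kind:` comment line.
#' @return An [hb_spectrum()].
#' @export
read_spectrum <- function(path, kind = NULL) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  km <- grep("^#\\s*kind:", meta, value = TRUE)
  if (is.null(kind)) {
    if (!length(km))
      stop("no '# kind:' line in file and no kind argument given", call. = FALSE)
    kind <- trimws(sub("^#\\s*kind:\\s*", "", km[1L]))
  }
  body <- lines[!grepl("^#", lines)]
  sep <- if (grepl("\t", body[1L])) "\t" else ","
  d <- utils::read.table(text = body, header = TRUE, sep = sep)
  if (!all(c("wavelength_nm", "value") %in% names(d)))
    stop("expected columns 'wavelength_nm' and 'value'", call. = FALSE)
  hb_spectrum(d$wavelength_nm, d$value, kind)
}

#' Write a spectrum to CSV
#'
#' Emits the dialect [read_spectrum()] reads: a `# kind:` comment line,
#' the `wavelength_nm,value` header, and values formatted to 9
#' significant digits so repeated writes are bit-stable.
#'
#' @param s An [hb_spectrum()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(s, path) {
  if (!inherits(s, "hb_spectrum")) stop("s must be an hb_spectrum", call. = FALSE)
  fmt <- function(x) formatC(x, format = "g", digits = 9)
  lines <- c(sprintf("# kind: %s", s$kind),
             "wavelength_nm,value",
             paste(fmt(s$wavelength), fmt(s$value), sep = ","))
  writeLines(lines, path)
  invisible(path)
}
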