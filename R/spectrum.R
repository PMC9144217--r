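# Spectrum container: the central exchange object of the pipeline.

#' Construct a spectrum
#'
#' A spectrum is a pair of equal-length vectors: a strictly increasing
#' frequency grid and the absorbance (or spectral density) sampled on it,
#' together with a unit tag for the frequency axis and free-form provenance
#' metadata.
#'
#' @param freqs Strictly increasing numeric frequency grid.
#' @param values Numeric absorbance values, same length as `freqs`.
#' @param unit Frequency unit, `"THz"` or `"wavenumber"` (cm^-1).
#' @param metadata Named list of provenance information (seeds, sources, ...).
#' @return An object of class `"spectrum"`.
#' @examples
#' s <- spectrum(seq(0.1, 1, by = 0.1), 1 + 2 * seq(0.1, 1, by = 0.1))
#' s
#' @export
spectrum <- function(freqs, values, unit = c("THz", "wavenumber"),
                     metadata = list()) {
  unit <- match.arg(unit)
  freqs <- as.numeric(freqs)
  values <- as.numeric(values)
  if (length(freqs) != length(values))
    stop("freqs and values must have the same length (", length(freqs),
         " vs ", length(values), ")")
  if (length(freqs) < 2L)
    stop("a spectrum needs at least 2 points")
  if (any(!is.finite(freqs)) || any(!is.finite(values)))
    stop("non-finite entries in spectrum")
  if (any(diff(freqs) <= 0))
    stop("frequency grid must be strictly increasing")
  structure(list(freqs = freqs, values = values, unit = unit,
                 metadata = metadata),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %d points, %.6g-%.6g %s\n",
              length(x$freqs), min(x$freqs), max(x$freqs), x$unit))
  invisible(x)
}

#' @export
length.spectrum <- function(x) length(x$freqs)

#' @rdname spectrum
#' @param x Object to test.
#' @export
is.spectrum <- function(x) inherits(x, "spectrum")

same_grid <- function(a, b, tol = 1e-9) {
  length(a$freqs) == length(b$freqs) &&
    a$unit == b$unit &&
    all(abs(a$freqs - b$freqs) <= tol * pmax(1, abs(a$freqs)))
}

stop_grid_mismatch <- function(a, b, what_a = "first", what_b = "second") {
  stop(sprintf(
    "frequency grids differ: %s spectrum has %d points on [%.6g, %.6g] %s; %s has %d points on [%.6g, %.6g] %s",
    what_a, length(a$freqs), min(a$freqs), max(a$freqs), a$unit,
    what_b, length(b$freqs), min(b$freqs), max(b$freqs), b$unit))
}

# Speed of light in cm/s; fixes the THz <-> wavenumber conversion factor.
.c_cm_s <- 2.99792458e10

#' Convert between THz and wavenumber
#'
#' `thz_to_wavenumber()` maps a frequency in THz to cm^-1 via
#' \eqn{\tilde\nu = f \cdot 10^{12} / c} with \eqn{c} in cm/s;
#' `wavenumber_to_thz()` is the exact inverse. 1 THz = 33.3564 cm^-1, so the
#' 0.1-15 THz band corresponds to roughly 3-500 cm^-1.
#'
#' @param f Frequency in THz (non-negative).
#' @param nu Wavenumber in cm^-1 (non-negative).
#' @return Converted numeric vector.
#' @examples
#' thz_to_wavenumber(1)    # 33.356...
#' wavenumber_to_thz(500)  # ~15 THz
#' @export
thz_to_wavenumber <- function(f) {
  if (any(f < 0)) stop("negative frequency not allowed")
  f * 1e12 / .c_cm_s
}

#' @rdname thz_to_wavenumber
#' @export
wavenumber_to_thz <- function(nu) {
  if (any(nu < 0)) stop("negative wavenumber not allowed")
  nu * .c_cm_s / 1e12
}

#' Convert a spectrum's frequency axis
#'
#' @param s A [spectrum()].
#' @param unit Target unit, `"THz"` or `"wavenumber"`.
#' @return Spectrum on the converted grid (values untouched).
#' @export
convert_unit <- function(s, unit = c("THz", "wavenumber")) {
  unit <- match.arg(unit)
  stopifnot(is.spectrum(s))
  if (s$unit == unit) return(s)
  freqs <- if (unit == "wavenumber") thz_to_wavenumber(s$freqs)
           else wavenumber_to_thz(s$freqs)
  spectrum(freqs, s$values, unit = unit, metadata = s$metadata)
}

# linear interpolation of a spectrum at a single frequency; errors off-grid
interp_value <- function(s, freq) {
  if (freq < min(s$freqs) || freq > max(s$freqs))
    stop(sprintf("frequency %.6g %s outside grid span [%.6g, %.6g]",
                 freq, s$unit, min(s$freqs), max(s$freqs)))
  stats::approx(s$freqs, s$values, xout = freq)$y
}

#' Read a two-column spectrum file
#'
#' Reads CSV or TSV with columns `frequency,absorbance`. Lines starting with
#' `#` are treated as metadata comments; a `# unit: THz` (or `wavenumber`)
#' line sets the frequency unit, other `# key: value` lines populate the
#' metadata map. The delimiter (comma or tab) is auto-detected from the
#' header line.
#'
#' @param path File to read.
#' @return A [spectrum()].
#' @export
read_spectrum <- function(path) {
  lines <- readLines(path)
  comments <- grep("^\\s*#", lines, value = TRUE)
  body <- grep("^\\s*#", lines, invert = TRUE, value = TRUE)
  body <- body[nzchar(trimws(body))]
  if (length(body) < 2L) stop("no data rows in ", path)
  sep <- if (grepl("\t", body[1])) "\t" else ","
  df <- utils::read.table(text = body, header = TRUE, sep = sep)
  if (ncol(df) < 2L) stop("expected two columns in ", path)
  meta <- list()
  unit <- "THz"
  for (cm in comments) {
    m <- regmatches(cm, regexec("^\\s*#\\s*([^:]+):\\s*(.*)$", cm))[[1]]
    if (length(m) == 3L) {
      key <- trimws(m[2]); val <- trimws(m[3])
      if (identical(key, "unit")) unit <- val else meta[[key]] <- val
    }
  }
  if (!unit %in% c("THz", "wavenumber"))
    stop("unknown unit tag '", unit, "' in ", path)
  spectrum(df[[1]], df[[2]], unit = unit, metadata = meta)
}

#' Write a spectrum to CSV
#'
#' Emits `# unit:` and `# key: value` metadata comments followed by a
#' `frequency,absorbance` table, the format [read_spectrum()] reads back.
#'
#' @param s A [spectrum()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(s, path) {
  stopifnot(is.spectrum(s))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# unit: %s", s$unit), con)
  for (key in names(s$metadata))
    writeLines(sprintf("# %s: %s", key, format(s$metadata[[key]])), con)
  writeLines("frequency,absorbance", con)
  writeLines(sprintf("%.12g,%.12g", s$freqs, s$values), con)
  invisible(path)
}
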