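# Baseline translation, normalization, linear fits, slope comparison, and
# the displaced-volume solvent-subtraction model for cell suspensions.

#' Translate a spectrum to a common origin
#'
#' Shifts all absorbance values by a constant so that the value at
#' `anchor_freq` (linearly interpolated if off-grid) equals `anchor_value`.
#' Used to bring measured spectra to a common origin, e.g. absorbance 1 a.u.
#' at 0.18 THz, before comparing their slopes. Translation leaves the fitted
#' slope unchanged.
#'
#' @param s A [spectrum()].
#' @param anchor_freq Anchor frequency, in the spectrum's unit; must lie
#'   within the grid span.
#' @param anchor_value Target value at the anchor (default 1).
#' @return Translated spectrum.
#' @export
translate_to_origin <- function(s, anchor_freq = 0.18, anchor_value = 1) {
  stopifnot(is.spectrum(s))
  shift <- anchor_value - interp_value(s, anchor_freq)
  spectrum(s$freqs, s$values + shift, unit = s$unit,
           metadata = c(s$metadata, list(translated_anchor = anchor_freq)))
}

#' Normalize a spectrum to its value at a point
#'
#' Divides the whole spectrum by its (interpolated) value at `anchor_freq`,
#' so the output equals 1 there. Simulated spectra are conventionally
#' normalized to their first point (0.029 THz) before comparison, which
#' removes any unknown global prefactor of the spectral-density calculation.
#'
#' @inheritParams translate_to_origin
#' @return Normalized spectrum.
#' @export
normalize_to_point <- function(s, anchor_freq = 0.029) {
  stopifnot(is.spectrum(s))
  v0 <- interp_value(s, anchor_freq)
  if (!is.finite(v0) || v0 == 0)
    stop(sprintf("cannot normalize: value at %.6g %s is %s",
                 anchor_freq, s$unit, format(v0)))
  spectrum(s$freqs, s$values / v0, unit = s$unit,
           metadata = c(s$metadata, list(normalized_anchor = anchor_freq)))
}

#' Fit a line to a spectrum over a frequency range
#'
#' Ordinary least squares of absorbance on frequency restricted to
#' `[fmin, fmax]`. THz absorbance of cell suspensions and of simulated
#' protein spectra grows linearly with frequency in the sub-THz band, so the
#' slope is the scalar summary compared across conditions.
#'
#' @param s A [spectrum()].
#' @param fmin,fmax Fit range bounds in the spectrum's unit. Defaults span
#'   the whole grid.
#' @return A `linear_fit` object: `slope`, `intercept`, `r_squared`,
#'   `slope_stderr`, `fit_range`, `n`.
#' @export
fit_linear <- function(s, fmin = min(s$freqs), fmax = max(s$freqs)) {
  stopifnot(is.spectrum(s))
  sel <- s$freqs >= fmin & s$freqs <= fmax
  if (sum(sel) < 3L)
    stop("need at least 3 points in [", fmin, ", ", fmax, "], got ", sum(sel))
  x <- s$freqs[sel]; y <- s$values[sel]
  fit <- stats::lm(y ~ x)
  sm <- suppressWarnings(summary(fit))  # "perfect fit" on noiseless fixtures
  r2 <- if (all(y == y[1])) 1 else sm$r.squared  # constant y: exact fit
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2,
                 slope_stderr = unname(sm$coefficients[2, 2]),
                 fit_range = c(fmin, fmax),
                 n = sum(sel)),
            class = "linear_fit")
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf("<linear_fit> slope %.6g +/- %.3g, intercept %.6g, R^2 %.6f (n=%d on [%.4g, %.4g])\n",
              x$slope, x$slope_stderr, x$intercept, x$r_squared, x$n,
              x$fit_range[1], x$fit_range[2]))
  invisible(x)
}

#' Compare two samples of spectral slopes
#'
#' One-sided Welch two-sample t-test that the mean slope of `fits_a` exceeds
#' that of `fits_b`. Inputs may be `linear_fit` objects (their `slope`
#' fields are used) or plain numerics. This is the statistical backing for
#' statements of the form "spectra in condition A have significantly larger
#' slopes than in condition B".
#'
#' @param fits_a,fits_b Lists of `linear_fit` objects or numeric vectors of
#'   slopes.
#' @param alternative `"greater"` (default: mean A > mean B), `"less"` or
#'   `"two.sided"`.
#' @return List with `p_value`, `statistic`, `df`, `mean_a`, `mean_b`.
#' @export
compare_slopes <- function(fits_a, fits_b, alternative = "greater") {
  pull <- function(fits) {
    if (is.numeric(fits)) return(as.numeric(fits))
    vapply(fits, function(f) {
      if (inherits(f, "linear_fit")) f$slope else as.numeric(f)
    }, numeric(1))
  }
  a <- pull(fits_a); b <- pull(fits_b)
  if (length(a) < 1L || length(b) < 1L) stop("both slope samples must be non-empty")
  if ((length(a) < 2L || stats::var(a) == 0) &&
      (length(b) < 2L || stats::var(b) == 0))
    stop("slope samples carry no variance; cannot test")
  ht <- stats::t.test(a, b, alternative = alternative, var.equal = FALSE)
  list(p_value = unname(ht$p.value), statistic = unname(ht$statistic),
       df = unname(ht$parameter), mean_a = mean(a), mean_b = mean(b))
}

#' Cell-suspension model
#'
#' Describes a suspension of approximately spherical cells for
#' solvent-baseline subtraction. The displaced solvent-volume fraction is
#' \eqn{f = \rho \cdot (\pi/6) d^3} with the cell density \eqn{\rho} in
#' cells/mL and the diameter \eqn{d} converted to cm. At the standard
#' experimental density of 3e7 cells/mL and a 20 um cell diameter,
#' f = 0.1257, i.e. the cells displace ~12.56% of the solvent volume.
#'
#' @param cell_density Cells per mL (>= 0).
#' @param cell_diameter Cell diameter in micrometres (> 0).
#' @return A `suspension_model` with the derived `displaced_fraction`.
#' @examples
#' suspension_model(3e7, 20)$displaced_fraction  # ~0.1257
#' @export
suspension_model <- function(cell_density = 3e7, cell_diameter = 20) {
  if (cell_density < 0) stop("cell density must be >= 0")
  if (cell_diameter <= 0) stop("cell diameter must be > 0")
  f <- displaced_volume_fraction(cell_density, cell_diameter)
  structure(list(cell_density = cell_density, cell_diameter = cell_diameter,
                 displaced_fraction = f),
            class = "suspension_model")
}

#' @export
print.suspension_model <- function(x, ...) {
  cat(sprintf("<suspension_model> %.4g cells/mL, d = %.4g um -> displaced fraction %.4f (%.2f%%)\n",
              x$cell_density, x$cell_diameter, x$displaced_fraction,
              100 * x$displaced_fraction))
  invisible(x)
}

#' @rdname suspension_model
#' @export
displaced_volume_fraction <- function(cell_density, cell_diameter) {
  d_cm <- cell_diameter * 1e-4            # um -> cm; 1 mL = 1 cm^3
  f <- cell_density * (pi / 6) * d_cm^3
  if (f >= 1)
    stop(sprintf("displaced fraction %.3f >= 1: nonphysical suspension", f))
  f
}

#' Subtract the solvent baseline from a suspension spectrum
#'
#' Under the additivity assumption the measured absorbance of a suspension
#' is `(1 - fraction) * solvent + cells`: the cells displace a fraction of
#' the solvent, and the remainder solvent forms the baseline. The cell
#' contribution is recovered as `sample - (1 - fraction) * solvent`.
#'
#' @param sample Suspension [spectrum()].
#' @param solvent Solvent-only [spectrum()] on the identical grid.
#' @param fraction Displaced volume fraction in `[0, 1)`; either a number or
#'   a [suspension_model()].
#' @return The cell-contribution spectrum.
#' @export
subtract_solvent <- function(sample, solvent, fraction) {
  stopifnot(is.spectrum(sample), is.spectrum(solvent))
  if (inherits(fraction, "suspension_model")) fraction <- fraction$displaced_fraction
  if (fraction < 0 || fraction >= 1) stop("fraction must be in [0, 1)")
  if (!same_grid(sample, solvent))
    stop_grid_mismatch(sample, solvent, "sample", "solvent")
  spectrum(sample$freqs, sample$values - (1 - fraction) * solvent$values,
           unit = sample$unit,
           metadata = c(sample$metadata, list(displaced_fraction = fraction)))
}
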