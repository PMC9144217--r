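# THz/IR spectral density from a molecular-dipole time series via the
# autocorrelation / Wiener-Khinchin route, over running trajectory windows.

#' Dipole time series
#'
#' A uniformly sampled 3-vector dipole signal, the raw material for
#' simulated THz spectra. The convention matching 1-ns spectral windows is
#' `dt = 0.2` ps and 5000 frames per window.
#'
#' @param dt Sampling interval in ps (> 0).
#' @param mu Numeric matrix with 3 columns (mu_x, mu_y, mu_z), one row per
#'   frame; arbitrary dipole units.
#' @param t0 Start time in ns.
#' @param metadata Named list of provenance.
#' @return A `dipole_series`.
#' @export
dipole_series <- function(dt, mu, t0 = 0, metadata = list()) {
  mu <- as.matrix(mu)
  if (ncol(mu) != 3) stop("mu must have 3 columns (mux, muy, muz)")
  if (nrow(mu) < 2) stop("need at least 2 frames")
  if (dt <= 0) stop("dt must be > 0")
  if (any(!is.finite(mu))) stop("non-finite dipole entries")
  structure(list(dt = dt, mu = mu, t0 = t0, metadata = metadata),
            class = "dipole_series")
}

#' @export
print.dipole_series <- function(x, ...) {
  cat(sprintf("<dipole_series> %d frames, dt = %.4g ps, t0 = %.4g ns (span %.4g ns)\n",
              nrow(x$mu), x$dt, x$t0, nrow(x$mu) * x$dt * 1e-3))
  invisible(x)
}

#' Read/write dipole CSV
#'
#' Format: columns `t_ps,mux,muy,muz`; `#` comment lines carry metadata as
#' for spectra. The time column must be uniformly sampled.
#'
#' @param path File path.
#' @return `read_dipole()` returns a [dipole_series()]; `write_dipole()`
#'   returns `path` invisibly.
#' @export
read_dipole <- function(path) {
  lines <- readLines(path)
  body <- grep("^\\s*#", lines, invert = TRUE, value = TRUE)
  df <- utils::read.csv(text = body)
  need <- c("t_ps", "mux", "muy", "muz")
  if (!all(need %in% names(df)))
    stop("dipole CSV must have columns ", paste(need, collapse = ", "))
  dts <- diff(df$t_ps)
  if (any(abs(dts - dts[1]) > 1e-6 * dts[1]))
    stop("time column is not uniformly sampled")
  dipole_series(dt = dts[1], mu = as.matrix(df[, c("mux", "muy", "muz")]),
                t0 = df$t_ps[1] * 1e-3)
}

#' @rdname read_dipole
#' @param d A [dipole_series()].
#' @export
write_dipole <- function(d, path) {
  stopifnot(inherits(d, "dipole_series"))
  con <- file(path, "w")
  on.exit(close(con))
  for (key in names(d$metadata))
    if (is.atomic(d$metadata[[key]]) && length(d$metadata[[key]]) == 1)
      writeLines(sprintf("# %s: %s", key, format(d$metadata[[key]])), con)
  writeLines("t_ps,mux,muy,muz", con)
  t <- d$t0 * 1e3 + (seq_len(nrow(d$mu)) - 1) * d$dt
  writeLines(sprintf("%.10g,%.12g,%.12g,%.12g",
                     t, d$mu[, 1], d$mu[, 2], d$mu[, 3]), con)
  invisible(path)
}

#' Dipole autocorrelation function
#'
#' C(tau) = < mu(t) . mu(t + tau) > averaged over the available time
#' origins, after removal of the mean dipole; the dot product sums the three
#' Cartesian components. C(0) equals the (population) variance of mu, i.e.
#' the mean squared fluctuation.
#'
#' @param d A [dipole_series()].
#' @param max_lag Largest lag in frames (< number of frames).
#' @return Data frame with `lag_ps` and `acf` columns.
#' @export
autocorrelation <- function(d, max_lag = nrow(d$mu) - 1L) {
  stopifnot(inherits(d, "dipole_series"))
  n <- nrow(d$mu)
  if (max_lag >= n) stop("max_lag (", max_lag, ") must be < n_frames (", n, ")")
  x <- sweep(d$mu, 2, colMeans(d$mu))
  # FFT-based linear ACF per component (zero-padded to avoid wraparound)
  m <- 2^ceiling(log2(2 * n))
  acf_tot <- numeric(max_lag + 1L)
  for (k in 1:3) {
    xp <- c(x[, k], rep(0, m - n))
    r <- Re(stats::fft(Mod(stats::fft(xp))^2, inverse = TRUE)) / m
    acf_tot <- acf_tot + r[1:(max_lag + 1L)]
  }
  acf_tot <- acf_tot / (n - 0:max_lag)  # average over available origins
  data.frame(lag_ps = (0:max_lag) * d$dt, acf = acf_tot)
}

# apodization windows; "bh3" = three-term Blackman-Harris, matching the
# post-processing applied to the measured spectra
apodization_window <- function(n, kind = c("bh3", "hann", "none")) {
  kind <- match.arg(kind)
  if (kind == "none") return(rep(1, n))
  k <- seq_len(n) - 1
  if (kind == "hann") return(0.5 - 0.5 * cos(2 * pi * k / (n - 1)))
  a <- c(0.42323, 0.49755, 0.07922)
  a[1] - a[2] * cos(2 * pi * k / (n - 1)) + a[3] * cos(4 * pi * k / (n - 1))
}

#' Spectral density of a dipole series
#'
#' Power spectrum of the mean-removed dipole signal by the Wiener-Khinchin
#' route: the FFT of the autocorrelation equals |FFT of the signal|^2 / N,
#' so the periodogram is computed directly from the signal in O(N log N).
#' The three Cartesian components are summed. The one-sided density is
#' scaled so that, with no apodization, its sum over the full band equals
#' the signal variance (Parseval). The frequency resolution is `1/(n*dt)`
#' and the grid is reported in cm^-1.
#'
#' @param d A [dipole_series()].
#' @param max_freq Truncation frequency in cm^-1 (<= Nyquist); default 80.
#'   `Inf` keeps the full band up to Nyquist.
#' @param apodization `"bh3"` (three-term Blackman-Harris, default),
#'   `"hann"`, or `"none"`. Apodization suppresses leakage at the cost of
#'   exact Parseval conservation.
#' @return A [spectrum()] with unit `"wavenumber"`.
#' @export
spectral_density <- function(d, max_freq = 80,
                             apodization = c("bh3", "hann", "none")) {
  stopifnot(inherits(d, "dipole_series"))
  apodization <- match.arg(apodization)
  n <- nrow(d$mu)
  nyq_thz <- 1 / (2 * d$dt)
  nyq_cm <- thz_to_wavenumber(nyq_thz)
  if (max_freq > nyq_cm && is.finite(max_freq))
    stop(sprintf("max_freq %.4g cm^-1 beyond Nyquist %.4g cm^-1 (dt = %.4g ps)",
                 max_freq, nyq_cm, d$dt))
  x <- sweep(d$mu, 2, colMeans(d$mu))
  w <- apodization_window(n, apodization)
  # normalize window power so a white signal keeps its variance
  w <- w / sqrt(mean(w^2))
  power <- numeric(n)
  for (k in 1:3) power <- power + Mod(stats::fft(x[, k] * w))^2
  power <- power / n^2            # sum over ALL n bins = variance (Parseval)
  nh <- floor(n / 2)
  one_sided <- power[1:(nh + 1)]
  # fold negative frequencies onto positive ones
  if (n %% 2 == 0) {
    if (nh >= 2) one_sided[2:nh] <- one_sided[2:nh] + rev(power[(nh + 2):n])
  } else {
    one_sided[2:(nh + 1)] <- one_sided[2:(nh + 1)] + rev(power[(nh + 2):n])
  }
  freq_thz <- (0:nh) / (n * d$dt)             # ps^-1 == THz
  freq_cm <- thz_to_wavenumber(freq_thz)
  keep <- freq_cm <= min(max_freq, nyq_cm)
  # drop DC: mean removal zeroes it and downstream normalization divides
  keep[1] <- FALSE
  spectrum(freq_cm[keep], one_sided[keep], unit = "wavenumber",
           metadata = list(dt_ps = d$dt, n_frames = n,
                           apodization = apodization,
                           resolution_cm = thz_to_wavenumber(1 / (n * d$dt))))
}

#' Window specification for running spectra
#'
#' @param width Window width in ns.
#' @param stride Stride between window starts in ns.
#' @param range_start,range_end Analysis range in ns; `NULL` means the
#'   start/end of the series the spec is applied to.
#' @return A `window_spec`.
#' @export
window_spec <- function(width = 1, stride = 0.2, range_start = NULL,
                        range_end = NULL) {
  if (width <= 0 || stride <= 0) stop("width and stride must be > 0")
  if (!is.null(range_end) && !is.null(range_start) &&
      range_end - range_start < width)
    stop("window width exceeds the analysis range")
  structure(list(width = width, stride = stride, range_start = range_start,
                 range_end = range_end),
            class = "window_spec")
}

#' Spectra over running trajectory windows
#'
#' Splits the dipole series into running windows (half-open `[start,
#' start + width)` in time; boundary frames belong to the later window) and
#' computes one spectral density per window. With the default 1-ns window,
#' 0.2-ns stride over an 8-ns range this yields 36 windows of 5000 frames
#' each at `dt = 0.2` ps.
#'
#' @param d A [dipole_series()].
#' @param w A [window_spec()]; a `NULL` `range_end` means the series end.
#' @param max_freq,apodization Passed to [spectral_density()].
#' @return A `spectral_window_set`: list with `windows` (data frame of
#'   start/end ns) and `spectra` (list of [spectrum()] on a common grid).
#' @export
windowed_spectra <- function(d, w = window_spec(), max_freq = 80,
                             apodization = "bh3") {
  stopifnot(inherits(d, "dipole_series"), inherits(w, "window_spec"))
  n <- nrow(d$mu)
  span_end <- d$t0 + n * d$dt * 1e-3
  r0 <- if (is.null(w$range_start)) d$t0 else w$range_start
  r1 <- if (is.null(w$range_end)) span_end else w$range_end
  if (r1 > span_end + 1e-9 || r0 < d$t0 - 1e-9)
    stop(sprintf("window range [%.4g, %.4g] ns outside series span [%.4g, %.4g] ns",
                 r0, r1, d$t0, span_end))
  if (r1 - r0 < w$width) stop("window width exceeds the analysis range")
  n_win <- floor((r1 - r0 - w$width) / w$stride + 1e-9) + 1L
  starts <- r0 + (seq_len(n_win) - 1) * w$stride
  frames_per_win <- round(w$width * 1e3 / d$dt)
  spectra <- vector("list", n_win)
  for (i in seq_len(n_win)) {
    i0 <- round((starts[i] - d$t0) * 1e3 / d$dt) + 1L
    idx <- i0:(i0 + frames_per_win - 1L)
    sub <- dipole_series(dt = d$dt, mu = d$mu[idx, , drop = FALSE],
                         t0 = starts[i])
    spectra[[i]] <- spectral_density(sub, max_freq = max_freq,
                                     apodization = apodization)
  }
  structure(list(windows = data.frame(start_ns = starts,
                                      end_ns = starts + w$width),
                 spectra = spectra),
            class = "spectral_window_set")
}

#' @export
print.spectral_window_set <- function(x, ...) {
  cat(sprintf("<spectral_window_set> %d windows, %.4g-%.4g ns\n",
              nrow(x$windows), min(x$windows$start_ns), max(x$windows$end_ns)))
  invisible(x)
}
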