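# Spectral convergence by dynamic time warping: exact band-constrained DTW
# (cDTW) and the multiresolution FastDTW approximation.

new_dtw_result <- function(cost, pi, pj, method, param) {
  structure(list(distance = sqrt(cost),
                 cost = cost,
                 path = cbind(i = pi, j = pj),
                 method = method,
                 param = param),
            class = "dtw_result")
}

#' @export
print.dtw_result <- function(x, ...) {
  cat(sprintf("<dtw_result> %s distance %.6g (path length %d)\n",
              x$method, x$distance, nrow(x$path)))
  invisible(x)
}

# Sakoe-Chiba window adapted to unequal lengths: row i admits columns within
# half-width w of the stretched diagonal j = i * m/n.
sakoe_chiba_window <- function(n, m, w) {
  i <- seq_len(n)
  centre <- i * m / n
  lo <- pmax(1L, as.integer(ceiling(centre - w)))
  hi <- pmin(m, as.integer(floor(centre + w)))
  lo[1] <- 1L
  hi[n] <- m
  lo <- pmin(lo, hi)
  list(lo = lo, hi = hi)
}

#' Exact constrained DTW distance
#'
#' Dynamic-programming optimum over warping paths inside a Sakoe-Chiba band
#' of half-width `ceil(band_fraction * max(n, m))`. The local cost is the
#' squared difference and the reported distance is the square root of the
#' accumulated cost, i.e. the Euclidean distance along the optimal warping
#' path. `band_fraction = 1` gives unconstrained DTW.
#'
#' @param a,b Numeric value series (length >= 2), or [spectrum()] objects
#'   (their values are compared).
#' @param band_fraction Band half-width as a fraction of the longer series.
#' @return A `dtw_result` with `distance`, accumulated `cost`, the warping
#'   `path` (two-column matrix of 1-based indices), `method`, and `param`.
#' @export
dtw_distance <- function(a, b, band_fraction = 0.1) {
  a <- series_values(a); b <- series_values(b)
  n <- length(a); m <- length(b)
  if (n < 2 || m < 2) stop("both series must have length >= 2")
  if (band_fraction <= 0) stop("band_fraction must be > 0")
  w <- ceiling(band_fraction * max(n, m))
  win <- sakoe_chiba_window(n, m, w)
  res <- dtw_window_cpp(a, b, win$lo, win$hi)
  new_dtw_result(res$cost, res$i, res$j, "cdtw",
                 c(band_fraction = band_fraction))
}

series_values <- function(x) {
  if (is.spectrum(x)) x$values else as.numeric(x)
}

reduce_by_half <- function(x) {
  n <- length(x)
  nh <- ceiling(n / 2)
  out <- numeric(nh)
  for (k in seq_len(nh)) {
    i <- 2 * k - 1
    out[k] <- if (i + 1 <= n) (x[i] + x[i + 1]) / 2 else x[i]
  }
  out
}

# Project a coarse path onto the fine grid and dilate by `radius`,
# expressed as per-row column ranges (a contiguous superset window).
expand_window <- function(path, n, m, radius) {
  lo <- rep.int(m, n); hi <- rep.int(1L, n)
  mark <- function(ii, jj) {
    ii <- ii[ii >= 1 & ii <= n]
    for (i in ii) {
      js <- pmax(1L, min(jj)); je <- pmin(m, max(jj))
      if (js < lo[i]) lo[i] <<- js
      if (je > hi[i]) hi[i] <<- je
    }
  }
  for (r in seq_len(nrow(path))) {
    ci <- path[r, 1]; cj <- path[r, 2]
    ii <- (2 * ci - 1 - radius):(2 * ci + radius)
    jj <- (2 * cj - 1 - radius):(2 * cj + radius)
    mark(ii, jj)
  }
  # guarantee global connectivity and the two corners
  lo[1] <- 1L; hi[n] <- m
  for (i in seq_len(n)) if (lo[i] > hi[i]) { lo[i] <- hi[i] }
  # windows of consecutive rows must overlap or touch for a path to exist
  for (i in 2:n) if (lo[i] > hi[i - 1] + 1L) lo[i] <- hi[i - 1]
  list(lo = pmax(1L, as.integer(lo)), hi = pmin(m, as.integer(hi)))
}

#' FastDTW approximate distance
#'
#' Multiresolution approximation of DTW with linear time and space: the
#' series are recursively coarsened by pairwise averaging, the coarse
#' optimal path is projected back and dilated by `radius`, and the exact
#' dynamic program is solved inside that narrow window. The result is an
#' upper bound on (never below) the exact DTW optimum.
#'
#' @inheritParams dtw_distance
#' @param radius Window dilation radius (>= 0); larger is more accurate.
#' @return A `dtw_result` with method `"fastdtw"`.
#' @export
fastdtw_distance <- function(a, b, radius = 1) {
  a <- series_values(a); b <- series_values(b)
  if (radius < 0) stop("radius must be >= 0")
  n <- length(a); m <- length(b)
  if (n < 2 || m < 2) stop("both series must have length >= 2")
  res <- fastdtw_rec(a, b, radius)
  new_dtw_result(res$cost, res$i, res$j, "fastdtw", c(radius = radius))
}

fastdtw_rec <- function(a, b, radius) {
  n <- length(a); m <- length(b)
  min_size <- radius + 2L
  if (n <= min_size || m <= min_size || n <= 3L || m <= 3L) {
    win <- sakoe_chiba_window(n, m, max(n, m))  # full window: exact DTW
    return(dtw_window_cpp(a, b, win$lo, win$hi))
  }
  coarse <- fastdtw_rec(reduce_by_half(a), reduce_by_half(b), radius)
  win <- expand_window(cbind(coarse$i, coarse$j), n, m, radius)
  dtw_window_cpp(a, b, win$lo, win$hi)
}

#' Convergence report for windowed spectra
#'
#' Quantifies whether spectra computed over running trajectory windows have
#' stopped changing. Each window's spectrum is normalized to its first grid
#' point, DTW distances are computed between window pairs (consecutive
#' pairs by default), and the report gives the distance range together with
#' a percentile-based verdict: the spectra are called convergent when the
#' empirical 95th percentile of the distances is at or below `tolerance`,
#' and the reported confidence level is the largest of 90/95/99 whose
#' percentile bound passes. The raw distances are returned so other
#' criteria can be applied.
#'
#' @param ws A `spectral_window_set` from [windowed_spectra()], or a plain
#'   list of [spectrum()] objects on a common grid.
#' @param method `"cdtw"` (exact, banded) or `"fastdtw"`.
#' @param tolerance Distance tolerance; `NULL` (default) uses 3x the median
#'   pairwise distance, a scale-free heuristic for stationary series.
#' @param pairs `"consecutive"` (window i vs i+1, default) or `"all"`.
#' @param band_fraction Band half-width fraction for `"cdtw"`.
#' @param radius Dilation radius for `"fastdtw"`.
#' @param normalize Normalize each spectrum before comparison (default
#'   `TRUE`).
#' @param anchor_freq Normalization anchor in the spectra's unit; `NULL`
#'   (default) uses each spectrum's first grid point. When the spectra have
#'   a resolved low-frequency anchor (e.g. 0.029 THz = 0.967 cm^-1 for
#'   simulated spectra) pass it here: normalizing at an unresolved noise
#'   bin makes distances meaninglessly large.
#' @return A `convergence_report`: method, number of windows, the vector of
#'   `distances`, `min`, `max`, `tolerance`, `confidence_level` (NA when
#'   even the 90th percentile exceeds tolerance) and the `converged` flag.
#' @export
convergence_report <- function(ws, method = c("cdtw", "fastdtw"),
                               tolerance = NULL,
                               pairs = c("consecutive", "all"),
                               band_fraction = 0.1, radius = 1,
                               normalize = TRUE, anchor_freq = NULL) {
  method <- match.arg(method)
  pairs <- match.arg(pairs)
  spectra <- if (inherits(ws, "spectral_window_set")) ws$spectra else ws
  k <- length(spectra)
  if (k < 3) stop("need at least 3 windows, got ", k)
  if (normalize)
    spectra <- lapply(spectra, function(s)
      normalize_to_point(s, anchor_freq = if (is.null(anchor_freq))
        s$freqs[1] else anchor_freq))
  dist_fun <- function(x, y) {
    if (method == "cdtw") dtw_distance(x, y, band_fraction)$distance
    else fastdtw_distance(x, y, radius)$distance
  }
  if (pairs == "consecutive") {
    idx <- cbind(seq_len(k - 1), 2:k)
  } else {
    idx <- t(utils::combn(k, 2))
  }
  distances <- vapply(seq_len(nrow(idx)), function(r)
    dist_fun(spectra[[idx[r, 1]]], spectra[[idx[r, 2]]]), numeric(1))
  if (is.null(tolerance)) tolerance <- 3 * stats::median(distances)
  levels <- c(99, 95, 90)
  bounds <- stats::quantile(distances, levels / 100, names = FALSE)
  pass <- bounds <= tolerance
  conf <- if (any(pass)) levels[which(pass)[1]] else NA_real_
  structure(list(method = method, n_windows = k, pairs = pairs,
                 distances = distances,
                 min = min(distances), max = max(distances),
                 tolerance = tolerance,
                 confidence_level = conf,
                 converged = bounds[levels == 95] <= tolerance),
            class = "convergence_report")
}

#' @export
print.convergence_report <- function(x, ...) {
  cat(sprintf("<convergence_report> %s over %d windows (%s pairs)\n",
              x$method, x$n_windows, x$pairs))
  cat(sprintf("  Euclidean distances: min %.6g, max %.6g (tolerance %.6g)\n",
              x$min, x$max, x$tolerance))
  cat(sprintf("  converged: %s (confidence level %s%%)\n",
              x$converged, format(x$confidence_level)))
  invisible(x)
}
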