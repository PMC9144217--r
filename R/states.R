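# Quasi-stable state decomposition of a ligand RMSD time series:
# histogram -> multi-Gaussian peak fit -> occupancies from areas ->
# per-frame state assignment -> representative frames.

#' Frequency counts of an RMSD series
#'
#' Histograms the RMSD values with a fixed bin width (0.05 Angstrom is the
#' conventional choice for ligand displacement analysis). Bins cover the
#' observed range and counts sum to the number of frames.
#'
#' @param s An [rmsd_series()] or numeric vector.
#' @param bin_width Bin width in Angstrom (> 0).
#' @return List with `centers`, `counts`, `bin_width`, `n`.
#' @export
histogram_counts <- function(s, bin_width = 0.05) {
  values <- if (inherits(s, "rmsd_series")) s$values else as.numeric(s)
  if (length(values) == 0) stop("empty series")
  if (bin_width <= 0) stop("bin_width must be > 0")
  lo <- floor(min(values) / bin_width) * bin_width
  nbin <- max(1L, ceiling((max(values) - lo) / bin_width + 1e-12))
  idx <- pmin(floor((values - lo) / bin_width) + 1L, nbin)
  counts <- tabulate(idx, nbin)
  list(centers = lo + (seq_len(nbin) - 0.5) * bin_width,
       counts = counts, bin_width = bin_width, n = length(values))
}

# area-parameterized Gaussian: A/(sigma sqrt(2 pi)) exp(-(x-xc)^2/(2 sigma^2)),
# scaled by bin width so the fitted A is in frame counts
gauss_mix <- function(x, centers, sigmas, areas, bin_width) {
  y <- numeric(length(x))
  for (i in seq_along(centers))
    y <- y + areas[i] / (sigmas[i] * sqrt(2 * pi)) *
      exp(-(x - centers[i])^2 / (2 * sigmas[i]^2)) * bin_width
  y
}

# initial centers: local maxima of a 5-bin moving-average smoothed
# histogram, keeping only maxima above 5% of the tallest peak (suppresses
# spurious noise bumps in sparsely populated tails)
detect_peaks <- function(hist, min_rel_height = 0.05) {
  counts <- hist$counts
  n <- length(counts)
  sm <- stats::filter(counts, rep(1 / 5, 5), sides = 2)
  sm[is.na(sm)] <- counts[is.na(sm)]
  sm <- as.numeric(sm)
  is_max <- vapply(seq_len(n), function(i) {
    l <- max(1, i - 2); r <- min(n, i + 2)
    sm[i] == max(sm[l:r]) && sm[i] >= min_rel_height * max(sm)
  }, logical(1))
  idx <- which(is_max)
  # collapse plateaus / maxima closer than 3 bins
  if (length(idx) > 1) idx <- idx[c(TRUE, diff(idx) > 2)]
  hist$centers[idx]
}

#' Multi-Gaussian peak fit of an RMSD histogram
#'
#' Nonlinear least squares of a sum of area-parameterized Gaussians to the
#' frequency counts. State occupancies are the fitted areas normalized to
#' 100%; this follows the convention of reading residence from the area
#' under each peak rather than from hard frame assignment. Component sigmas
#' are bounded below by half the bin width to prevent delta-spike
#' degeneracy. When no center guess is supplied, initial centers are the
#' local maxima of a 5-bin moving-average smoothed histogram and
#' `n_components` defaults to their count.
#'
#' @param hist Histogram from [histogram_counts()].
#' @param n_components Number of Gaussian components; `NULL` = number of
#'   detected local maxima.
#' @param init Optional numeric vector of center guesses (Angstrom).
#' @param max_iter Maximum optimizer iterations.
#' @return A `state_decomposition`: `components` data frame (center,
#'   center_stderr, sigma, amplitude, area) ordered by center, `occupancy`
#'   percentages summing to 100, `fitted` curve on the histogram grid,
#'   `r_squared`, `bin_width`, `n`.
#' @export
fit_peaks <- function(hist, n_components = NULL, init = NULL,
                      max_iter = 200) {
  x <- hist$centers; y <- hist$counts
  if (is.null(init)) {
    init <- detect_peaks(hist)
    if (length(init) == 0) init <- x[which.max(y)]
    if (!is.null(n_components)) {
      if (length(init) >= n_components) {
        # keep the n_components most prominent maxima
        h <- y[match(vapply(init, function(ci) which.min(abs(x - ci)),
                            integer(1)), seq_along(x))]
        init <- sort(init[order(h, decreasing = TRUE)][seq_len(n_components)])
      } else {
        # spread extra components over the data range
        extra <- stats::quantile(rep(x, y),
                                 probs = seq(0.1, 0.9,
                                             length.out = n_components - length(init)))
        init <- sort(c(init, as.numeric(extra)))
      }
    }
  }
  k <- length(init)
  if (!is.null(n_components) && k != n_components)
    stop("init length must equal n_components")
  if (k < 1) stop("need at least one component")
  if (length(x) < 3 * k)
    stop("too few bins (", length(x), ") for ", k, " components")

  bw <- hist$bin_width
  sigma0 <- rep(max(3 * bw, diff(range(x)) / (8 * k)), k)
  # initial areas from counts near each center
  area0 <- vapply(init, function(ci) {
    sum(y[abs(x - ci) <= 2 * sigma0[1]]) * 0.8 + 1
  }, numeric(1))

  # parameters: (centers, log sigmas-excess, log areas) packed
  sig_min <- bw / 2
  pack <- function(c_, s_, a_) c(c_, log(s_ - sig_min + 1e-12), log(a_))
  unpack <- function(p) {
    list(centers = p[1:k],
         sigmas = exp(p[(k + 1):(2 * k)]) + sig_min,
         areas = exp(p[(2 * k + 1):(3 * k)]))
  }
  resid_fun <- function(p) {
    q <- unpack(p)
    y - gauss_mix(x, q$centers, q$sigmas, q$areas, bw)
  }
  obj <- function(p) sum(resid_fun(p)^2)
  p0 <- pack(init, sigma0, area0)
  opt <- stats::optim(p0, obj, method = "BFGS",
                      control = list(maxit = max_iter, reltol = 1e-12))
  opt2 <- stats::optim(opt$par, obj, method = "BFGS",
                       control = list(maxit = max_iter, reltol = 1e-12))
  if (opt2$value > opt$value) opt2 <- opt
  q <- unpack(opt2$par)
  res <- resid_fun(opt2$par)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - sum(res^2) / ss_tot else 1
  if (r2 < 0 || !is.finite(opt2$value))
    stop(sprintf("peak fit failed to converge (residual SS %.4g)", sum(res^2)))

  # center standard errors via the Jacobian of the residuals
  jac <- numeric_jacobian(resid_fun, opt2$par)
  dof <- max(length(y) - 3 * k, 1)
  s2 <- sum(res^2) / dof
  covp <- tryCatch(s2 * solve(crossprod(jac)), error = function(e) NULL)
  cen_se <- if (is.null(covp)) rep(NA_real_, k) else sqrt(pmax(diag(covp)[1:k], 0))

  ord <- order(q$centers)
  comps <- data.frame(center = q$centers[ord],
                      center_stderr = cen_se[ord],
                      sigma = q$sigmas[ord],
                      amplitude = q$areas[ord] / (q$sigmas[ord] * sqrt(2 * pi)),
                      area = q$areas[ord])
  occ <- 100 * comps$area / sum(comps$area)
  structure(list(components = comps, occupancy = occ,
                 fitted = gauss_mix(x, comps$center, comps$sigma, comps$area, bw),
                 r_squared = r2, bin_width = bw, n = hist$n),
            class = "state_decomposition")
}

numeric_jacobian <- function(f, p, eps = 1e-6) {
  f0 <- f(p)
  J <- matrix(0, length(f0), length(p))
  for (j in seq_along(p)) {
    h <- eps * max(1, abs(p[j]))
    pj <- p; pj[j] <- pj[j] + h
    J[, j] <- (f(pj) - f0) / h
  }
  J
}

#' @export
print.state_decomposition <- function(x, ...) {
  cat(sprintf("<state_decomposition> %d states, R^2 = %.4f, bin %.3g A\n",
              nrow(x$components), x$r_squared, x$bin_width))
  for (i in seq_len(nrow(x$components)))
    cat(sprintf("  state %d: center %.2f +/- %.2f A, sigma %.2f A, occupancy %.2f%%\n",
                i, x$components$center[i],
                x$components$center_stderr[i],
                x$components$sigma[i], x$occupancy[i]))
  invisible(x)
}

#' Assign frames to states
#'
#' Labels each frame by the maximum-posterior component: Gaussian
#' likelihood at the frame's RMSD value weighted by the occupancy prior.
#' Exact posterior ties break deterministically to the lower-center state.
#'
#' @param s An [rmsd_series()] or numeric vector.
#' @param d A `state_decomposition` from [fit_peaks()].
#' @return Integer vector of state labels (1 = lowest center).
#' @export
assign_states <- function(s, d) {
  values <- if (inherits(s, "rmsd_series")) s$values else as.numeric(s)
  stopifnot(inherits(d, "state_decomposition"))
  k <- nrow(d$components)
  post <- vapply(seq_len(k), function(i)
    d$occupancy[i] * stats::dnorm(values, d$components$center[i],
                                  d$components$sigma[i]),
    numeric(length(values)))
  post <- matrix(post, ncol = k)
  # which.max on ties returns the first = lowest-center column
  apply(post, 1, which.max)
}

#' Representative frame per state
#'
#' For each fitted state, the frame whose RMSD is nearest the state center
#' (earliest frame on distance ties). This is the standard criterion for
#' picking structures representative of each quasi-stable pose: RMSD very
#' close to the state's mean value. States whose nearest frame is shared
#' with another assignment are still reported; states never visited (no
#' frame assigned) are reported as `NA`.
#'
#' @inheritParams assign_states
#' @param within_assigned If `TRUE` (default), candidates for a state are
#'   restricted to frames assigned to it by [assign_states()].
#' @return Data frame: `state`, `frame` (index, `NA` if never visited),
#'   `time_ns` (when the input carries times), `rmsd`, `center`.
#' @export
representative_frames <- function(s, d, within_assigned = TRUE) {
  values <- if (inherits(s, "rmsd_series")) s$values else as.numeric(s)
  times <- if (inherits(s, "rmsd_series")) s$times else rep(NA_real_, length(values))
  stopifnot(inherits(d, "state_decomposition"))
  labels <- if (within_assigned) assign_states(values, d) else NULL
  k <- nrow(d$components)
  out <- data.frame(state = seq_len(k), frame = NA_integer_,
                    time_ns = NA_real_, rmsd = NA_real_,
                    center = d$components$center)
  for (i in seq_len(k)) {
    cand <- if (within_assigned) which(labels == i) else seq_along(values)
    if (length(cand) == 0) next  # state never visited: reported missing
    dist <- abs(values[cand] - d$components$center[i])
    best <- cand[which.min(dist)]  # which.min: earliest on ties
    out$frame[i] <- best
    out$time_ns[i] <- times[best]
    out$rmsd[i] <- values[best]
  }
  out
}
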