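# Geometry and energetics over trajectories: Kabsch superposition,
# RMSD/RMSF, radial distribution functions, pairwise nonbonded energies.

#' Optimal superposition (Kabsch)
#'
#' Least-squares optimal proper rotation and translation mapping `mob` onto
#' `ref`, by SVD of the weighted covariance matrix with the determinant
#' corrected to +1 (no reflections). Returns the post-fit RMSD.
#'
#' @param ref,mob `N x 3` coordinate matrices, `N >= 3` non-collinear.
#' @param weights Optional non-negative per-atom weights.
#' @return List with `rotation` (3x3), `translation` (length 3; the fitted
#'   map is `mob %*% t(rotation) + translation`), and `rmsd` in Angstrom.
#' @export
kabsch_superpose <- function(ref, mob, weights = NULL) {
  ref <- as.matrix(ref); mob <- as.matrix(mob)
  stopifnot(ncol(ref) == 3, ncol(mob) == 3, nrow(ref) == nrow(mob))
  n <- nrow(ref)
  if (n < 3) stop("need at least 3 points")
  w <- if (is.null(weights)) rep(1, n) else weights
  if (length(w) != n || any(w < 0) || sum(w) == 0) stop("invalid weights")
  w <- w / sum(w)
  cr <- colSums(ref * w); cm <- colSums(mob * w)
  X <- sweep(mob, 2, cm); Y <- sweep(ref, 2, cr)
  H <- t(X * w) %*% Y
  sv <- svd(H)
  if (sv$d[2] < 1e-10 * max(sv$d[1], 1e-300))
    stop("degenerate (collinear or coincident) point set")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fitted <- X %*% t(R)
  rmsd <- sqrt(sum(w * rowSums((fitted - Y)^2)))
  list(rotation = R, translation = cr - as.vector(cm %*% t(R)), rmsd = rmsd)
}

#' Raw RMSD between two coordinate sets
#'
#' @param a,b `N x 3` matrices.
#' @return RMSD in Angstrom, with no superposition applied.
#' @export
rmsd_raw <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  stopifnot(all(dim(a) == dim(b)))
  sqrt(mean(rowSums((a - b)^2)))
}

#' RMSD time series over a trajectory
#'
#' Each frame is superposed on the reference frame using the alignment
#' selection (e.g. the TM2 helices of the channel), then the RMSD is
#' measured over the measurement selection (e.g. the ligand). This mirrors
#' the standard ligand-displacement analysis: align on the stable protein
#' core, measure the ligand.
#'
#' @param t A [trajectory()].
#' @param reference Reference frame index (default 1).
#' @param align_sel,measure_sel Atom index vectors (from [select_atoms()]);
#'   `NULL` uses all atoms.
#' @return An [rmsd_series()].
#' @export
rmsd_series_traj <- function(t, reference = 1L, align_sel = NULL,
                             measure_sel = NULL) {
  stopifnot(inherits(t, "trajectory"))
  if (is.null(align_sel)) align_sel <- seq_len(n_atoms(t))
  if (is.null(measure_sel)) measure_sel <- seq_len(n_atoms(t))
  ref_align <- matrix(t$coords[align_sel, , reference], ncol = 3)
  ref_meas <- matrix(t$coords[measure_sel, , reference], ncol = 3)
  nf <- n_frames(t)
  vals <- numeric(nf)
  for (f in seq_len(nf)) {
    fit <- kabsch_superpose(ref_align, matrix(t$coords[align_sel, , f], ncol = 3))
    moved <- matrix(t$coords[measure_sel, , f], ncol = 3) %*% t(fit$rotation)
    moved <- sweep(moved, 2, fit$translation, FUN = "+")
    vals[f] <- rmsd_raw(moved, ref_meas)
  }
  rmsd_series(times = (seq_len(nf) - 1) * t$dt * 1e-3, values = vals,
              align_selection = deparse(substitute(align_sel)),
              measure_selection = deparse(substitute(measure_sel)))
}

#' Per-atom root-mean-square fluctuation
#'
#' RMSF_i = sqrt(<|r_i - <r_i>|^2>) over the analysis range, after
#' superposing every frame onto the range-average structure (the standard
#' fluctuation definition; the average, not frame 1, is the reference).
#' The average structure is refined iteratively (two passes suffice for
#' well-behaved trajectories).
#'
#' @param t A [trajectory()].
#' @param selection Atom indices; `NULL` means all.
#' @param frames Frame index range to analyse; `NULL` means all frames.
#' @return Numeric vector of per-atom RMSF (Angstrom).
#' @export
rmsf <- function(t, selection = NULL, frames = NULL) {
  stopifnot(inherits(t, "trajectory"))
  if (is.null(selection)) selection <- seq_len(n_atoms(t))
  if (is.null(frames)) frames <- seq_len(n_frames(t))
  if (length(frames) < 2) stop("need at least 2 frames in range")
  X <- t$coords[selection, , frames, drop = FALSE]
  nf <- length(frames)
  mean_str <- X[, , 1]
  for (pass in 1:2) {
    aligned <- array(0, dim = dim(X))
    for (f in seq_len(nf)) {
      fit <- kabsch_superpose(mean_str, X[, , f])
      aligned[, , f] <- sweep(X[, , f] %*% t(fit$rotation), 2,
                              fit$translation, FUN = "+")
    }
    mean_str <- apply(aligned, c(1, 2), mean)
  }
  dev2 <- array(0, dim = c(dim(X)[1], nf))
  for (f in seq_len(nf))
    dev2[, f] <- rowSums((aligned[, , f] - mean_str)^2)
  sqrt(rowMeans(dev2))
}

#' Radial pair distribution function
#'
#' Histogram of a-b pair distances, averaged over frames and normalized by
#' the spherical-shell volume `4 pi r^2 dr` and by the number density of
#' group b, so an ideal gas gives g(r) = 1. With an orthorhombic box the
#' minimum-image convention is applied and `r_max` must not exceed half the
#' smallest box length; without a box, boundaries are open and the density
#' is estimated from the bounding box of the group-b coordinates.
#'
#' @param t A [trajectory()].
#' @param group_a,group_b Atom index vectors; self-pairs are excluded when
#'   the groups overlap.
#' @param bin_width Bin width in Angstrom.
#' @param r_max Histogram range in Angstrom.
#' @param frames Frame indices to average over; `NULL` means all.
#' @return An `rdf_profile`: `r` (bin centers), `g`, `density`, `bin_width`.
#' @export
rdf <- function(t, group_a, group_b, bin_width = 0.05, r_max = 10,
                frames = NULL) {
  stopifnot(inherits(t, "trajectory"))
  if (length(group_a) == 0 || length(group_b) == 0)
    stop("both groups must be non-empty")
  if (bin_width <= 0 || r_max <= 0) stop("bin_width and r_max must be > 0")
  if (!is.null(t$box) && r_max > min(t$box) / 2)
    stop(sprintf("r_max %.3g A exceeds half the smallest box length (%.3g A)",
                 r_max, min(t$box) / 2))
  if (is.null(frames)) frames <- seq_len(n_frames(t))
  nbin <- ceiling(r_max / bin_width)
  counts <- numeric(nbin)
  vol_est <- 0
  for (f in frames) {
    A <- matrix(t$coords[group_a, , f], ncol = 3)
    B <- matrix(t$coords[group_b, , f], ncol = 3)
    dx <- outer(A[, 1], B[, 1], "-")
    dy <- outer(A[, 2], B[, 2], "-")
    dz <- outer(A[, 3], B[, 3], "-")
    if (!is.null(t$box)) {
      dx <- dx - t$box[1] * round(dx / t$box[1])
      dy <- dy - t$box[2] * round(dy / t$box[2])
      dz <- dz - t$box[3] * round(dz / t$box[3])
    }
    r <- sqrt(dx^2 + dy^2 + dz^2)
    if (length(shared <- intersect(group_a, group_b)) > 0) {
      ia <- match(shared, group_a); ib <- match(shared, group_b)
      r[cbind(ia, ib)] <- NA  # exclude self-pairs
    }
    r <- r[!is.na(r) & r < r_max]
    counts <- counts + tabulate(pmin(floor(r / bin_width) + 1L, nbin), nbin)
    vol_est <- vol_est + if (!is.null(t$box)) prod(t$box) else {
      # open boundaries: rough density from the bounding box of all
      # coordinates (g(r) scale is then only approximate)
      ext <- pmax(apply(rbind(A, B), 2, function(v) diff(range(v))),
                  bin_width)
      prod(ext)
    }
  }
  vol <- vol_est / length(frames)
  if (vol <= 0) stop("cannot estimate volume for density normalization")
  rho <- length(group_b) / vol
  r_lo <- (seq_len(nbin) - 1) * bin_width
  shell <- 4 / 3 * pi * ((r_lo + bin_width)^3 - r_lo^3)
  norm <- length(group_a) * length(frames) * rho * shell
  structure(list(r = r_lo + bin_width / 2, g = counts / norm,
                 density = rho, bin_width = bin_width),
            class = "rdf_profile")
}

#' @export
print.rdf_profile <- function(x, ...) {
  cat(sprintf("<rdf_profile> %d bins of %.3g A, reference density %.4g A^-3\n",
              length(x$r), x$bin_width, x$density))
  invisible(x)
}

# Coulomb constant in kcal mol^-1 A e^-2 (force-field convention)
.coulomb_k <- 332.0636

# CHARMM-style switching function: 1 below switch_on, 0 above cutoff
switch_factor <- function(r, switch_on, cutoff) {
  s <- rep(1, length(r))
  s[r >= cutoff] <- 0
  mid <- r > switch_on & r < cutoff
  if (any(mid)) {
    c2 <- cutoff^2; s2 <- switch_on^2; r2 <- r[mid]^2
    s[mid] <- (c2 - r2)^2 * (c2 + 2 * r2 - 3 * s2) / (c2 - s2)^3
  }
  s
}

#' Pairwise nonbonded interaction energy
#'
#' Coulomb + Lennard-Jones interaction between two atom groups:
#' `elec = sum 332.0636 q_i q_j / r_ij` (kcal/mol with charges in e and
#' distances in Angstrom) and
#' `vdw = sum eps_ij [ (Rmin_ij/r)^12 - 2 (Rmin_ij/r)^6 ]` with
#' Lorentz-Berthelot-style combination (epsilon geometric-mean, Rmin
#' arithmetic-mean), smoothly switched to zero over `[switch_on, cutoff]`.
#' Intended for toy/fixture systems, not as a force-field engine.
#'
#' @param coords_a,coords_b `N x 3` coordinate matrices (Angstrom).
#' @param charges_a,charges_b Partial charges (e), one per atom.
#' @param lj_a,lj_b LJ parameters: data frame / list with `eps`
#'   (kcal/mol, >= 0) and `rmin` (Angstrom, per-atom Rmin/2 doubled, i.e.
#'   the pair minimum is `(rmin_i + rmin_j) / 2`). `NULL` disables LJ.
#' @param cutoff Distance cutoff in Angstrom (`Inf` = none).
#' @param switch_on Start of the switching region (default `0.9 * cutoff`).
#' @return An `energy_breakdown` list: `total`, `elec`, `vdw` (kcal/mol).
#' @export
nonbonded_energy <- function(coords_a, coords_b, charges_a, charges_b,
                             lj_a = NULL, lj_b = NULL, cutoff = Inf,
                             switch_on = 0.9 * cutoff) {
  A <- as.matrix(coords_a); B <- as.matrix(coords_b)
  na <- nrow(A); nb <- nrow(B)
  if (length(charges_a) != na || length(charges_b) != nb)
    stop("charge vectors must match atom counts")
  dx <- outer(A[, 1], B[, 1], "-")
  dy <- outer(A[, 2], B[, 2], "-")
  dz <- outer(A[, 3], B[, 3], "-")
  r <- sqrt(dx^2 + dy^2 + dz^2)
  if (any(r < 0.01))
    stop("overlapping atoms (pair distance < 0.01 A)")
  sw <- if (is.finite(cutoff)) switch_factor(r, switch_on, cutoff) else 1
  elec <- sum(.coulomb_k * outer(charges_a, charges_b) / r * sw)
  vdw <- 0
  if (!is.null(lj_a) && !is.null(lj_b)) {
    if (length(lj_a$eps) != na || length(lj_b$eps) != nb)
      stop("LJ parameter arrays must match atom counts")
    eps <- sqrt(outer(lj_a$eps, lj_b$eps))
    rmin <- outer(lj_a$rmin, lj_b$rmin, "+") / 2
    sr6 <- (rmin / r)^6
    vdw <- sum(eps * (sr6^2 - 2 * sr6) * sw)
  }
  structure(list(total = elec + vdw, elec = elec, vdw = vdw),
            class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat(sprintf("<energy_breakdown> total %.4f = elec %.4f + vdw %.4f kcal/mol\n",
              x$total, x$elec, x$vdw))
  invisible(x)
}

#' Per-segment statistics of an energy time series
#'
#' Arithmetic mean and sample standard deviation of each energy component
#' within user-defined time segments, e.g. before/after a binding event.
#'
#' @param series Data frame with columns `t_ps`, `total`, `elec`, `vdw`.
#' @param segments List of `c(start_ps, end_ps)` ranges (inclusive start,
#'   exclusive end; the final segment includes its end point).
#' @return Data frame: one row per segment per component with `mean`, `sd`,
#'   `n`.
#' @export
segment_stats <- function(series, segments) {
  need <- c("t_ps", "total", "elec", "vdw")
  if (!all(need %in% names(series)))
    stop("series must have columns ", paste(need, collapse = ", "))
  tmin <- min(series$t_ps); tmax <- max(series$t_ps)
  out <- list()
  for (k in seq_along(segments)) {
    seg <- segments[[k]]
    if (seg[1] < tmin - 1e-9 || seg[2] > tmax + 1e-9)
      stop(sprintf("segment [%g, %g] outside series span [%g, %g]",
                   seg[1], seg[2], tmin, tmax))
    last <- k == length(segments)
    sel <- series$t_ps >= seg[1] &
      (if (last) series$t_ps <= seg[2] else series$t_ps < seg[2])
    if (!any(sel)) stop(sprintf("segment [%g, %g] contains no samples",
                                seg[1], seg[2]))
    for (comp in c("total", "elec", "vdw")) {
      v <- series[[comp]][sel]
      out[[length(out) + 1L]] <- data.frame(
        segment = k, start_ps = seg[1], end_ps = seg[2], component = comp,
        mean = mean(v), sd = if (length(v) > 1) stats::sd(v) else 0,
        n = length(v))
    }
  }
  do.call(rbind, out)
}
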