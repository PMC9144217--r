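# Synthetic-data generators: every input the pipeline consumes, with the
# statistical structure the downstream analysis assumes.

#' Damped-cosine dipole model
#'
#' Specifies a synthetic molecular-dipole signal as a sum of exponentially
#' damped cosines plus white noise. The damped-cosine form is chosen because
#' its analytic spectrum (Lorentzian peaks) provides closed-form oracles for
#' the spectral-density machinery.
#'
#' @param modes List of modes, each `c(freq, amplitude, damping)`: frequency
#'   in THz (must be below the Nyquist frequency `1/(2*dt)`), amplitude in
#'   dipole units, damping rate in 1/ps. Mode directions cycle through the
#'   x, y, z axes.
#' @param noise_sigma Standard deviation of iid Gaussian noise added to each
#'   Cartesian component per frame.
#' @param dt Sampling interval in ps (0.2 ps matches 1-ns windows of 5000
#'   frames).
#' @param n_frames Number of frames (>= 2).
#' @param seed Integer RNG seed recorded in the output metadata.
#' @return A `dipole_model`.
#' @export
dipole_model <- function(modes = list(), noise_sigma = 0, dt = 0.2,
                         n_frames = 5000, seed = 1) {
  if (dt <= 0) stop("dt must be > 0")
  if (n_frames < 2) stop("n_frames must be >= 2")
  nyq <- 1 / (2 * dt)
  for (m in modes) {
    if (length(m) != 3) stop("each mode is c(freq_THz, amplitude, damping)")
    if (m[1] >= nyq)
      stop(sprintf("mode frequency %.4g THz >= Nyquist %.4g THz at dt = %.4g ps",
                   m[1], nyq, dt))
  }
  structure(list(modes = modes, noise_sigma = noise_sigma, dt = dt,
                 n_frames = as.integer(n_frames), seed = as.integer(seed)),
            class = "dipole_model")
}

#' Generate a dipole time series from a model
#'
#' Evaluates mu(t) = sum_i a_i exp(-gamma_i t) cos(2 pi f_i t) e_i + noise
#' on a uniform time grid. Reproducible: the same model (including seed)
#' yields a bit-identical series.
#'
#' @param model A [dipole_model()].
#' @param t0 Start time in ns, recorded on the series.
#' @return A [dipole_series()].
#' @export
gen_dipole <- function(model, t0 = 0) {
  stopifnot(inherits(model, "dipole_model"))
  set.seed(model$seed)
  n <- model$n_frames
  t <- (seq_len(n) - 1) * model$dt  # ps
  mu <- matrix(0, nrow = n, ncol = 3)
  for (i in seq_along(model$modes)) {
    m <- model$modes[[i]]
    axis <- ((i - 1) %% 3) + 1
    mu[, axis] <- mu[, axis] + m[2] * exp(-m[3] * t) * cos(2 * pi * m[1] * t)
  }
  if (model$noise_sigma > 0)
    mu <- mu + matrix(stats::rnorm(3 * n, sd = model$noise_sigma), ncol = 3)
  dipole_series(dt = model$dt, mu = mu, t0 = t0,
                metadata = list(seed = model$seed))
}

#' Markov state model for ligand RMSD series
#'
#' Describes a ligand RMSD signal that dwells in a small number of
#' quasi-stable states: a Markov chain over states whose stationary
#' distribution equals the target occupancies, with Gaussian emission around
#' each state's RMSD center. The chain (rather than iid draws) makes the
#' series visit states in contiguous epochs, as real binding/unbinding
#' trajectories do.
#'
#' @param centers State RMSD centers in Angstrom.
#' @param widths Emission standard deviations in Angstrom (> 0), recycled.
#' @param occupancies Target state occupancies, must sum to 1 (a vector of
#'   percentages summing to 100 is also accepted and rescaled).
#' @param transition_persistence Probability of remaining in the current
#'   state per step; default 0.999 per 0.2 ps step gives mean dwells of
#'   hundreds of ps.
#' @param dt Sampling interval in ps.
#' @param seed Integer RNG seed.
#' @return A `state_model`.
#' @export
state_model <- function(centers, widths, occupancies,
                        transition_persistence = 0.999, dt = 0.2, seed = 1) {
  k <- length(centers)
  widths <- rep_len(widths, k)
  if (length(occupancies) != k)
    stop("centers and occupancies must have the same length")
  if (sum(occupancies) > 2) occupancies <- occupancies / 100
  if (abs(sum(occupancies) - 1) > 0.01)
    stop("occupancies must sum to 1 (or 100%)")
  occupancies <- occupancies / sum(occupancies)  # absorb rounding (<=1%)
  if (any(widths <= 0)) stop("widths must be > 0")
  if (transition_persistence < 0 || transition_persistence > 1)
    stop("transition_persistence must be in [0, 1]")
  structure(list(centers = centers, widths = widths,
                 occupancies = occupancies,
                 transition_persistence = transition_persistence,
                 dt = dt, seed = as.integer(seed)),
            class = "state_model")
}

#' Generate a state-labelled RMSD series
#'
#' Simulates the Markov chain of a [state_model()]: from state i the chain
#' stays with probability p and otherwise jumps to a state drawn from the
#' stationary occupancies (transition matrix `p*I + (1-p)*1 pi^T`), so the
#' stationary distribution equals the target occupancies for any p < 1.
#' Emissions are `N(center_s, width_s^2)`.
#'
#' @param model A [state_model()].
#' @param n Number of frames (>= 1).
#' @return An `rmsd_series` (see [rmsd_series()]) with the extra field
#'   `states`, the per-frame true state labels.
#' @export
gen_state_series <- function(model, n) {
  stopifnot(inherits(model, "state_model"), n >= 1)
  set.seed(model$seed)
  k <- length(model$centers)
  p <- model$transition_persistence
  states <- integer(n)
  states[1] <- sample.int(k, 1, prob = model$occupancies)
  if (n > 1) {
    stay <- stats::runif(n - 1) < p
    jumps <- sample.int(k, n - 1, replace = TRUE, prob = model$occupancies)
    for (i in 2:n) states[i] <- if (stay[i - 1]) states[i - 1] else jumps[i - 1]
  }
  values <- stats::rnorm(n, mean = model$centers[states],
                         sd = model$widths[states])
  out <- rmsd_series(times = (seq_len(n) - 1) * model$dt * 1e-3,  # ps -> ns
                     values = pmax(values, 0),
                     metadata = list(seed = model$seed))
  out$states <- states
  out
}

#' Compose a suspension spectrum from solvent and cell contributions
#'
#' Forward model inverted by [subtract_solvent()]: the suspension absorbs as
#' `(1 - fraction) * solvent + cells`, i.e. the cells displace `fraction` of
#' the solvent volume and add their own absorbance on top of the remaining
#' solvent baseline.
#'
#' @param solvent,cells Spectra on identical grids.
#' @param fraction Displaced volume fraction in `[0, 1)`.
#' @return The suspension [spectrum()].
#' @export
gen_suspension_pair <- function(solvent, cells, fraction) {
  stopifnot(is.spectrum(solvent), is.spectrum(cells))
  if (fraction < 0 || fraction >= 1) stop("fraction must be in [0, 1)")
  if (!same_grid(solvent, cells))
    stop_grid_mismatch(solvent, cells, "solvent", "cells")
  spectrum(solvent$freqs, (1 - fraction) * solvent$values + cells$values,
           unit = solvent$unit,
           metadata = list(displaced_fraction = fraction))
}

#' Generate a toy coordinate trajectory
#'
#' Builds a reference configuration of `n_atoms` points uniform in a cubic
#' box, then produces frames as rigid-body transforms of the reference
#' (optional random rotation + translation per frame) plus isotropic
#' Gaussian jitter. Used to exercise superposition, RMSD/RMSF and RDF code
#' with known ground truth.
#'
#' @param n_atoms Number of atoms (>= 1).
#' @param n_frames Number of frames.
#' @param rigid_motion If `TRUE`, each frame gets a random rotation and a
#'   random translation (removable by superposition).
#' @param jitter_sigma Per-coordinate Gaussian jitter in Angstrom.
#' @param seed Integer RNG seed.
#' @param box Cubic box edge length in Angstrom; also the sampling volume
#'   of the reference configuration.
#' @param dt Frame spacing in ps.
#' @return A [trajectory()] with metadata recording the seed.
#' @export
gen_toy_trajectory <- function(n_atoms, n_frames, rigid_motion = FALSE,
                               jitter_sigma = 0, seed = 1, box = 20, dt = 0.2) {
  stopifnot(n_atoms >= 1, n_frames >= 1)
  set.seed(seed)
  ref <- matrix(stats::runif(3 * n_atoms, 0, box), ncol = 3)
  coords <- array(0, dim = c(n_atoms, 3, n_frames))
  for (f in seq_len(n_frames)) {
    x <- ref
    if (rigid_motion) {
      R <- random_rotation()
      shift <- stats::runif(3, -box / 4, box / 4)
      ctr <- colMeans(x)
      x <- sweep(x, 2, ctr) %*% t(R)
      x <- sweep(x, 2, ctr + shift, FUN = "+")
    }
    if (jitter_sigma > 0)
      x <- x + matrix(stats::rnorm(3 * n_atoms, sd = jitter_sigma), ncol = 3)
    coords[, , f] <- x
  }
  trajectory(coords, dt = dt,
             atoms = data.frame(name = rep("X", n_atoms),
                                resid = seq_len(n_atoms),
                                chain = rep("A", n_atoms),
                                stringsAsFactors = FALSE),
             box = if (rigid_motion) NULL else rep(box, 3),
             metadata = list(seed = seed, reference = ref,
                             jitter_sigma = jitter_sigma))
}

#' Stationary mode comb for dipole fixtures
#'
#' Builds a list of undamped modes on a regular frequency grid with
#' amplitudes `f^(power/2)`, so the spectral-density envelope grows as
#' `f^power` — emulating the linear-in-frequency rise of sub-THz protein
#' absorbance. Undamped (stationary) modes are required for running-window
#' fixtures: a damped cosine is a one-shot transient that later windows
#' never see.
#'
#' @param freqs Mode frequencies in THz.
#' @param power Envelope exponent; a stiffer system has a larger `power`.
#' @return List of `c(freq, amplitude, 0)` modes for [dipole_model()].
#' @export
mode_comb <- function(freqs = seq(0.029, 1.0, by = 0.05), power = 1) {
  lapply(freqs, function(f) c(f, f^(power / 2), 0))
}

# uniform random rotation matrix (QR of Gaussian matrix, det fixed to +1)
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  R <- qr.Q(qr_)
  d <- diag(sign(diag(qr.R(qr_))))
  R <- R %*% d
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

#' Materialize a full synthetic demo dataset
#'
#' Writes to `dir` every input format the pipeline consumes: a quartet of
#' experimental-style spectra (solvent, solvent+blocker, suspension,
#' suspension+blocker), two dipole series (apo and blocker-bound
#' conditions), a four-state ligand RMSD series, and a toy trajectory.
#'
#' @param dir Output directory (created if missing).
#' @param seed Integer seed controlling every generator.
#' @return Named list of the written file paths, invisibly.
#' @export
write_fixtures <- function(dir, seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  grid <- seq(0.1, 1.2, by = 0.01)
  susp <- suspension_model(3e7, 20)
  # linear-in-frequency absorbances; blocker-treated cells absorb more
  solvent  <- spectrum(grid, 0.5 + 6.0 * grid, metadata = list(role = "GM"))
  solventB <- spectrum(grid, 0.5 + 6.1 * grid, metadata = list(role = "GM+amiloride"))
  cells_u  <- spectrum(grid, 0.1 + 1.2 * grid)
  cells_t  <- spectrum(grid, 0.1 + 1.6 * grid)
  sampleU <- gen_suspension_pair(solvent, cells_u, susp$displaced_fraction)
  sampleT <- gen_suspension_pair(solventB, cells_t, susp$displaced_fraction)
  sampleU$metadata$role <- "GM+cells"
  sampleT$metadata$role <- "GM+cells+amiloride"

  # stationary mode combs with a rising power envelope S(f) ~ f^p; the
  # blocker-bound condition is stiffer (steeper envelope -> larger slope)
  dip_apo <- dipole_model(modes = mode_comb(power = 1.0),
                          noise_sigma = 0.02, dt = 0.2, n_frames = 25000,
                          seed = seed)
  dip_blk <- dipole_model(modes = mode_comb(power = 1.6),
                          noise_sigma = 0.02, dt = 0.2, n_frames = 25000,
                          seed = seed + 1)

  # persistence 0.995 (mean dwell ~40 ps) keeps contiguous state epochs but
  # gives enough dwell events at 20k frames for stable demo occupancies
  sm <- state_model(centers = c(3.19, 6.30, 8.33, 9.26), widths = 0.3,
                    occupancies = c(7.75, 29.34, 21.42, 41.46) / 100,
                    transition_persistence = 0.995, seed = seed)
  rmsd <- gen_state_series(sm, 20000)
  traj <- gen_toy_trajectory(50, 40, jitter_sigma = 0.1, seed = seed)

  paths <- list(
    solvent = file.path(dir, "spectrum_GM.csv"),
    solvent_blocker = file.path(dir, "spectrum_GM_amiloride.csv"),
    sample_untreated = file.path(dir, "spectrum_GM_cells.csv"),
    sample_treated = file.path(dir, "spectrum_GM_cells_amiloride.csv"),
    dipole_apo = file.path(dir, "dipole_apo.csv"),
    dipole_blocker = file.path(dir, "dipole_amiloride.csv"),
    rmsd = file.path(dir, "rmsd_ligand.csv"),
    trajectory = file.path(dir, "toy_trajectory.xyz"))
  write_spectrum(solvent, paths$solvent)
  write_spectrum(solventB, paths$solvent_blocker)
  write_spectrum(sampleU, paths$sample_untreated)
  write_spectrum(sampleT, paths$sample_treated)
  write_dipole(gen_dipole(dip_apo), paths$dipole_apo)
  write_dipole(gen_dipole(dip_blk), paths$dipole_blocker)
  utils::write.csv(data.frame(t_ns = rmsd$times, rmsd = rmsd$values),
                   paths$rmsd, row.names = FALSE)
  write_xyz(traj, paths$trajectory)
  invisible(paths)
}
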