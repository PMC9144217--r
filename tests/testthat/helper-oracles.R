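# Independent oracles used by the unit and acceptance tests. These are
# deliberately naive (brute force / closed form) and share no code with the
# implementation paths they check.

# O(N^2) autocorrelation of a 3-column signal, mean removed, averaged over
# available time origins.
brute_acf <- function(mu, max_lag) {
  x <- sweep(mu, 2, colMeans(mu))
  n <- nrow(x)
  vapply(0:max_lag, function(lag) {
    s <- 0
    for (t in seq_len(n - lag)) s <- s + sum(x[t, ] * x[t + lag, ])
    s / (n - lag)
  }, numeric(1))
}

# Direct periodogram by explicit DFT sums: one-sided, negative frequencies
# folded, scaled so the full-band sum equals the signal variance.
direct_periodogram <- function(mu) {
  x <- sweep(mu, 2, colMeans(mu))
  n <- nrow(x)
  t <- 0:(n - 1)
  power <- numeric(n)
  for (k in 0:(n - 1)) {
    w <- exp(-2i * pi * k * t / n)
    power[k + 1] <- sum(vapply(1:3, function(c) Mod(sum(x[, c] * w))^2,
                               numeric(1)))
  }
  power <- power / n^2
  nh <- floor(n / 2)
  one <- power[1:(nh + 1)]
  if (n %% 2 == 0) {
    if (nh >= 2) one[2:nh] <- one[2:nh] + rev(power[(nh + 2):n])
  } else {
    one[2:(nh + 1)] <- one[2:(nh + 1)] + rev(power[(nh + 2):n])
  }
  one
}

# Exhaustive enumeration of all monotone warping paths (steps right, down,
# diagonal) from (1,1) to (n,m); returns the minimal accumulated squared
# cost. Exponential -- only for series of length <= 8.
brute_dtw_cost <- function(a, b) {
  n <- length(a); m <- length(b)
  rec <- function(i, j) {
    c_ij <- (a[i] - b[j])^2
    if (i == 1 && j == 1) return(c_ij)
    best <- Inf
    if (i > 1) best <- min(best, rec(i - 1, j))
    if (j > 1) best <- min(best, rec(i, j - 1))
    if (i > 1 && j > 1) best <- min(best, rec(i - 1, j - 1))
    c_ij + best
  }
  rec(n, m)
}

# Full-matrix DP in plain R (no band): unconstrained DTW oracle.
full_dtw_cost <- function(a, b) {
  n <- length(a); m <- length(b)
  D <- matrix(Inf, n, m)
  D[1, 1] <- (a[1] - b[1])^2
  for (i in 1:n) for (j in 1:m) {
    if (i == 1 && j == 1) next
    prev <- c(if (i > 1) D[i - 1, j] else Inf,
              if (j > 1) D[i, j - 1] else Inf,
              if (i > 1 && j > 1) D[i - 1, j - 1] else Inf)
    D[i, j] <- (a[i] - b[j])^2 + min(prev)
  }
  D[n, m]
}

# Quaternion (Horn) method for optimal superposition RMSD: largest
# eigenvalue of the 4x4 key matrix built from the covariance of the
# centered point sets.
quaternion_rmsd <- function(ref, mob) {
  n <- nrow(ref)
  X <- sweep(mob, 2, colMeans(mob))
  Y <- sweep(ref, 2, colMeans(ref))
  S <- t(X) %*% Y
  K <- matrix(0, 4, 4)
  K[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  K[1, 2] <- K[2, 1] <- S[2, 3] - S[3, 2]
  K[1, 3] <- K[3, 1] <- S[3, 1] - S[1, 3]
  K[1, 4] <- K[4, 1] <- S[1, 2] - S[2, 1]
  K[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  K[2, 3] <- K[3, 2] <- S[1, 2] + S[2, 1]
  K[2, 4] <- K[4, 2] <- S[3, 1] + S[1, 3]
  K[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  K[3, 4] <- K[4, 3] <- S[2, 3] + S[3, 2]
  K[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  lambda <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(X^2) + sum(Y^2) - 2 * lambda) / n
  sqrt(max(msd, 0))
}

# Proper random rotation matrix for test constructions.
test_rotation <- function() {
  Q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# Trajectory of independent ideal-gas configurations (fresh uniform draw
# per frame, unlike gen_toy_trajectory which jitters one reference).
ideal_gas_trajectory <- function(n_atoms, n_frames, box = 20, seed = 1) {
  set.seed(seed)
  coords <- array(stats::runif(n_atoms * 3 * n_frames, 0, box),
                  dim = c(n_atoms, 3, n_frames))
  trajectory(coords, dt = 1, box = rep(box, 3))
}

# independent linear interpolation of a spectrum value
interp_value_for_test <- function(s, f) stats::approx(s$freqs, s$values, xout = f)$y
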