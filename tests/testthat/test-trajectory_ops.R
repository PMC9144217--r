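test_that("kabsch_superpose recovers rigid transforms and matches the quaternion oracle", {
  set.seed(41)
  ref <- matrix(rnorm(30, sd = 3), 10)
  R <- test_rotation()
  mob <- ref %*% t(R) + rep(c(1, -2, 0.5), each = 10)
  fit <- kabsch_superpose(ref, mob)
  expect_lt(fit$rmsd, 1e-9)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  # fitted map actually lands on ref
  moved <- sweep(mob %*% t(fit$rotation), 2, fit$translation, FUN = "+")
  expect_equal(moved, ref, tolerance = 1e-9)
  # raw 3-4-5 shift without alignment
  expect_equal(rmsd_raw(ref, ref + rep(c(3, 4, 0), each = 10)), 5,
               tolerance = 1e-12)
  # random clouds: rmsd equals the independent quaternion method to 1e-9
  for (rep in 1:10) {
    a <- matrix(rnorm(30), 10)
    b <- matrix(rnorm(30), 10)
    expect_equal(kabsch_superpose(a, b)$rmsd, quaternion_rmsd(a, b),
                 tolerance = 1e-9)
  }
  # invariance under global rotation/translation of both structures
  Q <- test_rotation()
  a <- matrix(rnorm(30), 10); b <- matrix(rnorm(30), 10)
  expect_equal(kabsch_superpose(a %*% t(Q) + 5, b %*% t(Q) + 5)$rmsd,
               kabsch_superpose(a, b)$rmsd, tolerance = 1e-9)
  expect_error(kabsch_superpose(matrix(1, 5, 3), matrix(1:15, 5)),
               "degenerate")
})

test_that("rmsd_series_traj aligns then measures, matching brute-force recomputation", {
  tr <- gen_toy_trajectory(30, 20, jitter_sigma = 0.1, seed = 7)
  rs <- rmsd_series_traj(tr)
  expect_lt(rs$values[1], 1e-12)            # reference frame vs itself
  # brute-force per-frame recomputation with independent quaternion fit
  ref <- tr$coords[, , 1]
  for (f in c(5, 13)) {
    expect_equal(rs$values[f], quaternion_rmsd(ref, tr$coords[, , f]),
                 tolerance = 1e-9)
  }
  # split selections: align on half, measure the other half
  rs2 <- rmsd_series_traj(tr, align_sel = 1:15, measure_sel = 16:30)
  expect_true(all(rs2$values >= 0))
  expect_lt(rs2$values[1], 1e-12)
})

test_that("rmsf captures isotropic fluctuation and relative domain stiffness", {
  # static trajectory: all zeros
  st <- trajectory(array(rep(matrix(rnorm(30), 10), 5), c(10, 3, 5)))
  expect_equal(max(rmsf(st)), 0, tolerance = 1e-12)
  # isotropic jitter sigma: RMSF -> sigma * sqrt(3)
  tr <- gen_toy_trajectory(150, 200, jitter_sigma = 0.2, seed = 9)
  expect_equal(mean(rmsf(tr)), 0.2 * sqrt(3), tolerance = 0.05)
  # two domains, one jittered: jittered domain strictly more mobile
  set.seed(10)
  base <- matrix(runif(60, 0, 10), 20)
  coords <- array(0, c(20, 3, 50))
  for (f in 1:50) {
    x <- base
    x[11:20, ] <- x[11:20, ] + matrix(rnorm(30, sd = 0.3), 10)
    coords[, , f] <- x
  }
  fl <- rmsf(trajectory(coords))
  expect_gt(mean(fl[11:20]), mean(fl[1:10]))
  expect_error(rmsf(tr, frames = 1L), "at least 2")
})

test_that("rdf is flat for an ideal gas and resolves discrete structure", {
  # independent uniform configurations: g(r) = 1 within 5%
  tr <- ideal_gas_trajectory(300, 12, box = 20, seed = 11)
  g <- rdf(tr, 1:300, 1:300, bin_width = 0.5, r_max = 9)
  mid <- g$r >= 2 & g$r <= 9 / 2
  expect_true(all(abs(g$g[mid] - 1) < 0.05))
  # neighbour-count integral consistency
  rho <- g$density
  counts <- cumsum(4 * pi * rho * g$r^2 * g$g * g$bin_width)
  expected <- 4 / 3 * pi * rho * (g$r + g$bin_width / 2)^3
  upper <- g$r >= 2 & g$r <= 6   # enough pairs for a stable ratio
  expect_true(all(abs(counts[upper] / expected[upper] - 1) < 0.05))
  # two fixed particles at 5 A: a single nonzero bin at 5 A
  two <- trajectory(array(c(0, 5, 0, 0, 0, 0), c(2, 3, 1)))
  g2 <- rdf(two, 1, 2, bin_width = 0.1, r_max = 8)
  expect_equal(sum(g2$g > 0), 1L)
  expect_equal(g2$r[g2$g > 0], 5.05, tolerance = 0.1)
  # simple-cubic lattice: first peaks at a and a*sqrt(2)
  a <- 3
  pts <- as.matrix(expand.grid(x = 0:4, y = 0:4, z = 0:4)) * a
  lat <- trajectory(array(pts, c(nrow(pts), 3, 1)), box = rep(5 * a, 3))
  gl <- rdf(lat, seq_len(nrow(pts)), seq_len(nrow(pts)),
            bin_width = 0.1, r_max = 7)
  peaks <- gl$r[order(gl$g, decreasing = TRUE)[1:2]]
  expect_equal(sort(peaks), c(a, a * sqrt(2)), tolerance = 0.1)
  expect_error(rdf(tr, 1:10, 1:10, r_max = 11), "half the smallest box")
})

test_that("nonbonded_energy reproduces the analytic Coulomb and LJ anchors", {
  # two unit charges at 1 A: 332.0636 kcal/mol
  e <- nonbonded_energy(matrix(0, 1, 3), matrix(c(1, 0, 0), 1, 3), 1, 1)
  expect_equal(e$elec, 332.0636, tolerance = 1e-7)
  expect_equal(e$total, e$elec + e$vdw, tolerance = 1e-9)
  # LJ pair at r = Rmin: energy exactly -eps
  lj <- list(eps = 0.25, rmin = 3.5)
  e2 <- nonbonded_energy(matrix(0, 1, 3), matrix(c(3.5, 0, 0), 1, 3),
                         0, 0, lj, lj)
  expect_equal(e2$vdw, -0.25, tolerance = 1e-10)
  # beyond cutoff: zero
  e3 <- nonbonded_energy(matrix(0, 1, 3), matrix(c(20, 0, 0), 1, 3), 1, 1,
                         lj, lj, cutoff = 12)
  expect_equal(e3$total, 0)
  # switching is continuous: just below cutoff the energy is tiny
  e4 <- nonbonded_energy(matrix(0, 1, 3), matrix(c(11.99, 0, 0), 1, 3),
                         1, 1, cutoff = 12)
  expect_lt(abs(e4$elec), 0.05)
  # pairwise additivity and group-swap symmetry
  set.seed(12)
  A <- matrix(rnorm(9, sd = 4), 3); B <- matrix(rnorm(12, sd = 4) + 10, 4)
  qa <- runif(3, -1, 1); qb <- runif(4, -1, 1)
  lja <- list(eps = runif(3, 0.05, 0.3), rmin = runif(3, 2, 4))
  ljb <- list(eps = runif(4, 0.05, 0.3), rmin = runif(4, 2, 4))
  ef <- nonbonded_energy(A, B, qa, qb, lja, ljb)
  er <- nonbonded_energy(B, A, qb, qa, ljb, lja)
  expect_equal(ef$total, er$total, tolerance = 1e-10)
  piecewise <- sum(vapply(1:3, function(i)
    nonbonded_energy(A[i, , drop = FALSE], B, qa[i], qb,
                     list(eps = lja$eps[i], rmin = lja$rmin[i]), ljb)$total,
    numeric(1)))
  expect_equal(ef$total, piecewise, tolerance = 1e-10)
  expect_error(nonbonded_energy(matrix(0, 1, 3), matrix(0.001, 1, 3), 1, 1),
               "overlapping")
})

test_that("segment_stats matches brute-force slice statistics", {
  # constant series: mean = value, sd = 0
  cs <- data.frame(t_ps = 0:49, total = -30, elec = -20, vdw = -10)
  st <- segment_stats(cs, list(c(0, 49)))
  expect_equal(st$mean[st$component == "total"], -30)
  expect_equal(st$sd, rep(0, 3))
  # two-level series: segment means recovered exactly
  tl <- data.frame(t_ps = 0:99, total = rep(c(-10, -40), each = 50),
                   elec = rep(c(-7, -30), each = 50),
                   vdw = rep(c(-3, -10), each = 50))
  s2 <- segment_stats(tl, list(c(0, 50), c(50, 99)))
  expect_equal(s2$mean[s2$segment == 1 & s2$component == "total"], -10)
  expect_equal(s2$mean[s2$segment == 2 & s2$component == "elec"], -30)
  # stochastic: mean of N(-30, 4^2), n = 100, within 3 SEM; oracle equality
  set.seed(13)
  ns <- data.frame(t_ps = 0:99, total = rnorm(100, -30, 4),
                   elec = rnorm(100, -20, 3), vdw = rnorm(100, -10, 2))
  s3 <- segment_stats(ns, list(c(0, 99)))
  expect_lt(abs(s3$mean[s3$component == "total"] + 30), 1.2)
  expect_equal(s3$mean[s3$component == "vdw"], mean(ns$vdw), tolerance = 1e-12)
  expect_equal(s3$sd[s3$component == "elec"], sd(ns$elec), tolerance = 1e-12)
  expect_error(segment_stats(ns, list(c(0, 200))), "outside series span")
})
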