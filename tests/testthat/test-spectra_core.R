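test_that("THz/wavenumber conversion matches the defining constant and round-trips", {
  expect_identical(thz_to_wavenumber(0), 0)
  expect_equal(thz_to_wavenumber(1), 1e12 / 2.99792458e10, tolerance = 1e-12)
  expect_equal(thz_to_wavenumber(1), 33.356, tolerance = 1e-4)
  expect_equal(thz_to_wavenumber(15), 500, tolerance = 2e-3)
  f <- c(0.029, 0.18, 1, 15, 80)
  expect_equal(wavenumber_to_thz(thz_to_wavenumber(f)), f, tolerance = 1e-12)
  expect_error(thz_to_wavenumber(-1), "negative")
  expect_error(wavenumber_to_thz(-1), "negative")
})

test_that("spectrum constructor enforces its invariants", {
  expect_error(spectrum(c(1, 2), 1:3), "same length")
  expect_error(spectrum(c(2, 1), 1:2), "strictly increasing")
  expect_error(spectrum(1, 1), "at least 2")
  s <- spectrum(1:5, 1:5, unit = "wavenumber")
  expect_s3_class(s, "spectrum")
  expect_equal(convert_unit(s, "THz")$freqs, wavenumber_to_thz(1:5))
  expect_equal(convert_unit(convert_unit(s, "THz"), "wavenumber")$freqs,
               s$freqs, tolerance = 1e-12)
})

test_that("spectrum CSV I/O round-trips values, unit and metadata", {
  s <- spectrum(seq(0.1, 1, 0.05), rnorm(19), unit = "THz",
                metadata = list(role = "GM"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectrum(s, path)
  r <- read_spectrum(path)
  expect_equal(r$freqs, s$freqs, tolerance = 1e-10)
  expect_equal(r$values, s$values, tolerance = 1e-10)
  expect_identical(r$unit, "THz")
  expect_identical(r$metadata$role, "GM")
})

test_that("translate_to_origin anchors the spectrum and preserves slope", {
  grid <- seq(0.1, 1.2, by = 0.01)
  s <- spectrum(grid, 2 + 5 * grid)
  tr <- translate_to_origin(s, 0.18, 1)
  expect_equal(interp_value_for_test(tr, 0.18), 1, tolerance = 1e-12)
  # already at 1 a.u. at anchor: unchanged
  expect_equal(translate_to_origin(tr, 0.18, 1)$values, tr$values)
  # constant spectrum to constant anchor value
  cs <- spectrum(grid, rep(5, length(grid)))
  expect_equal(unique(translate_to_origin(cs, 0.18, 1)$values), 1)
  # slope invariance under translation, noisy case
  set.seed(42)
  s2 <- spectrum(grid, 2 + 5 * grid + rnorm(length(grid), sd = 0.05))
  expect_equal(fit_linear(translate_to_origin(s2, 0.18, 1))$slope,
               fit_linear(s2)$slope, tolerance = 1e-12)
  expect_error(translate_to_origin(s, 5), "outside grid")
})

test_that("normalize_to_point is idempotent and rescales slope as 1/anchor value", {
  grid <- seq(0.029, 1, by = 0.01)
  a <- 2; b <- 3; f0 <- 0.029
  s <- spectrum(grid, a + b * grid)
  n1 <- normalize_to_point(s, f0)
  expect_equal(interp_value_for_test(n1, f0), 1, tolerance = 1e-12)
  expect_equal(normalize_to_point(n1, f0)$values, n1$values, tolerance = 1e-12)
  expect_equal(fit_linear(n1)$slope, b / (a + b * f0), tolerance = 1e-9)
  # spectrum equal to anchor value everywhere -> all ones
  cs <- spectrum(grid, rep(7, length(grid)))
  expect_equal(normalize_to_point(cs, f0)$values, rep(1, length(grid)))
  zs <- spectrum(grid, grid - 0.029)  # zero exactly at the anchor
  expect_error(normalize_to_point(zs, f0), "cannot normalize")
})

test_that("fit_linear recovers exact lines and matches closed-form OLS", {
  grid <- seq(0.18, 1, by = 0.02)
  s <- spectrum(grid, 2 * grid + 1)
  f <- fit_linear(s)
  expect_equal(f$slope, 2, tolerance = 1e-10)
  expect_equal(f$intercept, 1, tolerance = 1e-10)
  expect_equal(f$r_squared, 1, tolerance = 1e-10)
  expect_equal(fit_linear(spectrum(grid, rep(3, length(grid))))$slope, 0)
  expect_error(fit_linear(s, 0.18, 0.2), "at least 3")

  # noisy line: slope within 3 stderr of truth; OLS normal-equations oracle
  set.seed(7)
  for (rep in 1:5) {
    x <- sort(runif(50, 0.1, 1))
    y <- 2 * x + 1 + rnorm(50, sd = 0.1)
    fo <- fit_linear(spectrum(x, y))
    expect_lt(abs(fo$slope - 2), 3 * fo$slope_stderr)
    sxx <- sum((x - mean(x))^2)
    slope_ne <- sum((x - mean(x)) * (y - mean(y))) / sxx
    expect_equal(fo$slope, slope_ne, tolerance = 1e-10)
    expect_equal(fo$intercept, mean(y) - slope_ne * mean(x), tolerance = 1e-10)
  }
})

test_that("compare_slopes behaves as a one-sided location test", {
  set.seed(11)
  x <- rnorm(12, 10, 0.2)
  same <- compare_slopes(x, x)
  expect_equal(same$p_value, 0.5, tolerance = 1e-9)
  # slope samples at the two simulated-condition means, n = 10 each
  a <- rnorm(10, 11.77, 0.14)
  b <- rnorm(10, 10.56, 0.14)
  expect_lt(compare_slopes(a, b)$p_value, 0.05)
  expect_gt(compare_slopes(b, a)$p_value, 0.95)
  # one-sided complements sum to 1
  expect_equal(compare_slopes(a, b)$p_value +
                 compare_slopes(a, b, alternative = "less")$p_value,
               1, tolerance = 1e-9)
  expect_error(compare_slopes(1, 2), "no variance")
})

test_that("displaced_volume_fraction implements the sphere-packing formula", {
  # 3e7 cells/mL of 20-um spheres displace ~12.56% of the solvent
  expect_equal(displaced_volume_fraction(3e7, 20), 0.1257, tolerance = 1e-3)
  expect_equal(displaced_volume_fraction(0, 20), 0)
  expect_equal(displaced_volume_fraction(1e7, 10), 5.236e-3, tolerance = 1e-4)
  expect_error(displaced_volume_fraction(1e10, 20), "nonphysical")
  m <- suspension_model(3e7, 20)
  expect_equal(m$displaced_fraction, 3e7 * pi / 6 * (20e-4)^3)
  expect_error(suspension_model(-1, 20), ">= 0")
  expect_error(suspension_model(3e7, 0), "> 0")
})

test_that("subtract_solvent inverts the additive suspension model", {
  grid <- seq(0.1, 1, by = 0.01)
  solvent <- spectrum(grid, 0.5 + 6 * grid)
  # fraction 0, sample = solvent -> zero cells
  z <- subtract_solvent(solvent, solvent, 0)
  expect_equal(z$values, rep(0, length(grid)))
  # fraction f, sample = solvent -> cells = f * solvent
  f <- 0.1256
  c2 <- subtract_solvent(solvent, solvent, f)
  expect_equal(c2$values, f * solvent$values, tolerance = 1e-12)
  other <- spectrum(grid + 0.001, solvent$values)
  expect_error(subtract_solvent(solvent, other, 0.1), "grids differ")
  expect_error(subtract_solvent(solvent, solvent, 1), "\\[0, 1\\)")
})
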