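test_that("autocorrelation matches analytic forms and the brute-force oracle", {
  # constant dipole: zero ACF after mean removal
  d0 <- dipole_series(dt = 0.2, mu = matrix(3, nrow = 50, ncol = 3))
  expect_equal(max(abs(autocorrelation(d0, 20)$acf)), 0)
  # pure cosine along z: C(tau) proportional to cos(2 pi f tau)
  n <- 1000; dt <- 0.2; f <- 0.5
  t <- (0:(n - 1)) * dt
  dz <- dipole_series(dt, cbind(0, 0, cos(2 * pi * f * t)))
  ac <- autocorrelation(dz, 100)
  expect_gt(cor(ac$acf, cos(2 * pi * f * ac$lag_ps)), 0.999)
  # random series: equality with O(N^2) brute force to 1e-10
  set.seed(3)
  dr <- dipole_series(0.2, matrix(rnorm(90), ncol = 3))
  ac2 <- autocorrelation(dr, 15)
  expect_equal(ac2$acf, brute_acf(dr$mu, 15), tolerance = 1e-10)
  # C(0) equals the population variance of mu
  x <- sweep(dr$mu, 2, colMeans(dr$mu))
  expect_equal(ac2$acf[1], sum(x^2) / nrow(x), tolerance = 1e-10)
  expect_error(autocorrelation(dr, 30), "max_lag")
})

test_that("spectral_density locates pure modes to within one bin", {
  # 1 THz cosine at the canonical sampling: argmax at 33.36 cm^-1
  m <- dipole_model(modes = list(c(1, 1, 0)), dt = 0.2, n_frames = 5000,
                    seed = 1)
  s <- spectral_density(gen_dipole(m), max_freq = 80)
  res <- thz_to_wavenumber(1 / (5000 * 0.2))
  expect_lt(abs(s$freqs[which.max(s$values)] - thz_to_wavenumber(1)), res)
  # off-grid frequency still lands within one bin (any dt, n)
  for (pars in list(c(0.7313, 0.3, 1200), c(1.3177, 0.1, 3000))) {
    mm <- dipole_model(modes = list(c(pars[1], 1, 0)), dt = pars[2],
                       n_frames = pars[3], seed = 2)
    ss <- spectral_density(gen_dipole(mm), max_freq = Inf)
    res2 <- thz_to_wavenumber(1 / (pars[3] * pars[2]))
    expect_lt(abs(ss$freqs[which.max(ss$values)] - thz_to_wavenumber(pars[1])),
              res2)
  }
  expect_error(spectral_density(gen_dipole(m), max_freq = 1000), "Nyquist")
})

test_that("two on-grid cosines with amplitudes 1:2 give peak powers 1:4", {
  n <- 2000; dt <- 0.2
  # frequencies on the DFT grid so each mode occupies a single bin
  f1 <- 10 / (n * dt); f2 <- 100 / (n * dt)
  m <- dipole_model(modes = list(c(f1, 1, 0), c(f2, 2, 0)), dt = dt,
                    n_frames = n, seed = 1)
  s <- spectral_density(gen_dipole(m), max_freq = Inf, apodization = "none")
  p1 <- s$values[which.min(abs(s$freqs - thz_to_wavenumber(f1)))]
  p2 <- s$values[which.min(abs(s$freqs - thz_to_wavenumber(f2)))]
  expect_equal(p2 / p1, 4, tolerance = 1e-6)
})

test_that("Wiener-Khinchin route equals the direct periodogram oracle", {
  set.seed(17)
  d <- dipole_series(0.2, matrix(rnorm(3 * 100), ncol = 3))
  s <- spectral_density(d, max_freq = Inf, apodization = "none")
  expect_equal(s$values, direct_periodogram(d$mu)[-1], tolerance = 1e-8)
})

test_that("spectral density conserves variance and scales quadratically", {
  set.seed(5)
  mu <- matrix(rnorm(3 * 400), ncol = 3) +
    cbind(cos(2 * pi * 0.3 * (0:399) * 0.2), 0, 0)
  d <- dipole_series(0.2, mu)
  s <- spectral_density(d, max_freq = Inf, apodization = "none")
  x <- sweep(mu, 2, colMeans(mu))
  expect_equal(sum(s$values), sum(x^2) / nrow(x), tolerance = 1e-8)
  # invariance under constant dipole offset
  s_off <- spectral_density(dipole_series(0.2, mu + 10), max_freq = Inf,
                            apodization = "none")
  expect_equal(s_off$values, s$values, tolerance = 1e-10)
  # doubling the amplitude quadruples the density everywhere
  s2 <- spectral_density(dipole_series(0.2, 2 * mu), max_freq = Inf,
                         apodization = "none")
  expect_equal(s2$values, 4 * s$values, tolerance = 1e-10)
  # apodized variants too (window power is normalized)
  sb <- spectral_density(d, max_freq = Inf, apodization = "bh3")
  sb2 <- spectral_density(dipole_series(0.2, 2 * mu), max_freq = Inf,
                          apodization = "bh3")
  expect_equal(sb2$values, 4 * sb$values, tolerance = 1e-10)
})

test_that("windowed_spectra implements the stated window geometry", {
  # 8-ns series at 0.2 ps: 12-20 ns, 1-ns windows, 0.2-ns stride -> 36 windows
  d <- gen_dipole(dipole_model(modes = list(), noise_sigma = 1, dt = 0.2,
                               n_frames = 40000, seed = 1), t0 = 12)
  ws <- windowed_spectra(d, window_spec(1, 0.2, 12, 20), max_freq = 10)
  expect_equal(nrow(ws$windows), 36L)
  # each 1-ns window holds 5000 frames at 0.2 ps
  expect_equal(ws$spectra[[1]]$metadata$n_frames, 5000)
  # all windows share one grid
  grids <- vapply(ws$spectra, function(s) length(s$freqs), integer(1))
  expect_true(all(grids == grids[1]))
  # width = full range -> single window
  ws1 <- windowed_spectra(d, window_spec(8, 0.2, 12, 20), max_freq = 10)
  expect_equal(nrow(ws1$windows), 1L)
  expect_error(windowed_spectra(d, window_spec(1, 0.2, 0, 8), max_freq = 10),
               "outside series span")
  expect_error(window_spec(2, 0.2, 0, 1), "exceeds")
})

test_that("dipole CSV round-trips", {
  d <- gen_dipole(dipole_model(modes = list(c(0.4, 1, 0.1)),
                               noise_sigma = 0.1, dt = 0.2, n_frames = 50,
                               seed = 2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_dipole(d, path)
  r <- read_dipole(path)
  expect_equal(r$mu, d$mu, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(r$dt, d$dt, tolerance = 1e-9)
})
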