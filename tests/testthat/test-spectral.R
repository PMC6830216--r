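test_that("raised-cosine H(f): passband, stopband and transition values", {
  # impulse map has a flat spectrum, so |F(filtered)| reads H directly
  n <- 40  # 1/40 grid makes 0.20, 0.25 and 0.30 exactly representable
  a <- array(0, c(n, n, n)); a[21, 21, 21] <- 1
  m <- density_map(a, 1.0)
  filt <- lowpass_raised_cosine(m, filter_spec(4.0))  # f_c = 0.25, w = 0.02
  F1 <- fft(filt$data)
  f <- voxres:::radial_freq_grid(c(n, n, n))
  # oracle: closed-form H at exactly representable frequencies
  i_pass <- which(abs(f - 0.20) < 1e-12)  # below 0.25 - 0.01
  i_stop <- which(abs(f - 0.30) < 1e-12)  # above 0.25 + 0.01
  expect_true(length(i_pass) > 0 && length(i_stop) > 0)
  expect_equal(Mod(F1[i_pass]), rep(1, length(i_pass)), tolerance = 1e-9)
  expect_equal(Mod(F1[i_stop]), rep(0, length(i_stop)), tolerance = 1e-12)
  # mid-transition voxel: H = 0.5(1 + cos(pi (f - lo)/w))
  i_mid <- which(abs(f - 0.25) < 1e-12)
  expect_equal(Mod(F1[i_mid]), rep(0.5, length(i_mid)), tolerance = 1e-9)
})

test_that("lowpass preserves DC exactly and is all-pass on band-limited maps", {
  m <- fixture_map(20)
  filt <- lowpass_raised_cosine(m, filter_spec(4.0))
  expect_equal(mean(filt$data), mean(m$data), tolerance = 1e-12)
  # band-limit below the passband edge, then filtering is the identity
  pre <- lowpass_raised_cosine(m, filter_spec(8.0))
  again <- lowpass_raised_cosine(pre, filter_spec(4.0))
  expect_equal(again$data, pre$data,
               tolerance = 1e-5 * max(abs(pre$data)))
  expect_error(lowpass_raised_cosine(m, filter_spec(1.5)), "Nyquist",
               class = "voxres_validation_error")
})

test_that("lowpass cascade equals the stronger filter; energy never grows", {
  m <- fixture_map(24)
  a <- lowpass_raised_cosine(lowpass_raised_cosine(m, 4), 9)
  b <- lowpass_raised_cosine(m, 9)
  expect_equal(a$data, b$data, tolerance = 1e-9 * max(abs(b$data)))
  for (d in c(3, 6, 12)) {
    filt <- lowpass_raised_cosine(m, d)
    expect_lte(sum(filt$data^2), sum(m$data^2))
  }
})

test_that("bfactor: closed-form gain, identity at B=0, inverse pair", {
  expect_equal(measured_bfactor_gain(-60, 0.25), exp(60 * 0.25^2 / 4),
               tolerance = 1e-6)
  expect_equal(measured_bfactor_gain(100, 0.125), exp(-100 * 0.125^2 / 4),
               tolerance = 1e-6)
  m <- fixture_map(20)
  expect_identical(bfactor_apply(m, 0)$data, m$data)
  back <- bfactor_apply(bfactor_apply(m, -60), 60)
  expect_equal(back$data, m$data, tolerance = 1e-4 * max(abs(m$data)))
})

test_that("phase randomization preserves amplitudes, keeps output real", {
  m <- fixture_map(20)
  pr <- phase_randomize(m, beyond = 4, seed = 3)
  F0 <- Mod(fft(m$data)); F1 <- Mod(fft(pr$data))
  expect_equal(F1, F0, tolerance = 1e-6)
  # imaginary residue of the inverse transform is numerically zero
  imag_norm <- max(abs(Im(fft(fft(pr$data), inverse = TRUE) / length(pr$data))))
  expect_lt(imag_norm, 1e-6 * sqrt(sum(pr$data^2)))
  # low-frequency phases untouched
  f <- voxres:::radial_freq_grid(dim(m$data))
  keep <- f <= 1 / 4
  expect_equal(fft(pr$data)[keep], fft(m$data)[keep], tolerance = 1e-9)
  # determinism and non-triviality
  expect_identical(phase_randomize(m, 4, seed = 3)$data, pr$data)
  expect_gt(max(abs(pr$data - m$data)), 1e-3)
})

test_that("phase randomization beyond Nyquist edge changes nothing", {
  m <- fixture_map(16)
  pr <- phase_randomize(m, beyond = 2 * m$voxel_size, seed = 1)
  # only frequencies above 0.5 cycles/voxel would change; none exist
  expect_equal(pr$data, m$data, tolerance = 1e-9)
  expect_error(phase_randomize(m, 1.0), class = "voxres_validation_error")
})

test_that("resample: identity, constants, and analytic cosine oracle", {
  m <- fixture_map(16)
  expect_identical(resample(m, m$voxel_size)$data, m$data)
  cm <- density_map(array(2.5, c(32, 32, 32)), 1.0)
  half <- resample(cm, 2.0)
  expect_identical(dim(half$data), rep(16L, 3))
  expect_equal(as.numeric(half$data), rep(2.5, 16^3), tolerance = 1e-9)
  # cosine of period 8 A sampled at 1 A, resampled to 0.5 A
  n <- 32
  x <- (0:(n - 1))
  cosmap <- density_map(array(rep(cos(2 * pi * x / 8), n * n), c(n, n, n)), 1.0)
  up <- resample(cosmap, 0.5)
  expect_equal(dim(up$data)[1], 64L)
  x2 <- (0:63) * 0.5
  expected <- array(rep(cos(2 * pi * x2 / 8), 64 * 64), c(64, 64, 64))
  expect_equal(up$data, expected, tolerance = 0.01)
  expect_equal(up$voxel_size, 0.5)
  # too-small result guarded
  small <- density_map(array(1, c(16, 16, 16)), 1.0)
  expect_error(resample(small, 2.0), "13", class = "voxres_validation_error")
})

test_that("shell energy is invariant under phase randomization", {
  m <- fixture_map(18)
  pr <- phase_randomize(m, beyond = 5, seed = 2)
  e0 <- shell_energy(m); e1 <- shell_energy(pr)
  expect_equal(e1$energy, e0$energy, tolerance = 1e-9)
})
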