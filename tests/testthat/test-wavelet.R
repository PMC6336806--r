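test_that("frequency grid is log-spaced with the requested density", {
  p <- wavelet_params(0.001, 0.064, voices_per_octave = 16)
  f <- frequency_grid(p)
  expect_equal(max(f), 0.064)
  expect_equal(length(f), 6 * 16 + 1)       # 6 octaves inclusive
  expect_equal(unique(round(diff(log2(f)), 12)), 1 / 16)
  expect_error(wavelet_params(0.05, 0.01), "f_min")
  expect_error(wavelet_params(0.01, 0.05, voices_per_octave = 2), "voices")
})

test_that("transform is linear and zero on the zero signal", {
  set.seed(5)
  p <- wavelet_params(0.05, 0.2, voices_per_octave = 8)
  z <- uniform_series(rep(0, 256), fs_hz = 1)
  expect_true(all(Mod(morlet_cwt(z, p)$coeffs) == 0))
  a <- rnorm(256); b <- rnorm(256)
  Wa <- morlet_cwt(uniform_series(a, 1), p)$coeffs
  Wb <- morlet_cwt(uniform_series(b, 1), p)$coeffs
  Wab <- morlet_cwt(uniform_series(a + b, 1), p)$coeffs
  expect_lt(max(Mod(Wab - Wa - Wb)) / max(Mod(Wab)), 1e-10)
  Wsc <- morlet_cwt(uniform_series(3.7 * a, 1), p)$coeffs
  expect_lt(max(Mod(Wsc - 3.7 * Wa)) / max(Mod(Wsc)), 1e-10)
})

test_that("FFT path matches direct quadrature of the wavelet integral", {
  set.seed(7)
  g <- rnorm(64)
  ser <- uniform_series(g, fs_hz = 1)
  p <- wavelet_params(0.09, 0.25, voices_per_octave = 8)
  sc <- morlet_cwt(ser, p)
  ks <- round(seq(1, length(sc$freqs_hz), length.out = 5))
  for (k in ks) {
    ref <- cwt_quadrature(g, 1, sc$freqs_hz[k], t = 32)
    got <- sc$coeffs[k, 33]
    expect_lt(Mod(got - ref) / Mod(ref), 1e-3)
  }
})

test_that("a delayed input shifts coefficients in time (interior)", {
  set.seed(9)
  n <- 512
  x <- as.numeric(arima.sim(list(ar = 0.9), n + 32))
  p <- wavelet_params(0.05, 0.2, voices_per_octave = 8)
  W1 <- morlet_cwt(uniform_series(x[1:n] - mean(x[1:n]), 1), p)$coeffs
  d <- 32
  x2 <- x[(1 + d):(n + d)]
  W2 <- morlet_cwt(uniform_series(x2 - mean(x2), 1), p)$coeffs
  interior <- 150:350
  # W2[, t] corresponds to W1[, t + d]
  err <- Mod(W2[, interior] - W1[, interior + d])
  expect_lt(max(err) / max(Mod(W1[, interior + d])), 1e-2)
})

test_that("cone of influence follows the e-folding closed form and is monotone", {
  ser <- uniform_series(rnorm(1200), fs_hz = 1)
  p <- wavelet_params(1.5e-3, 0.05, voices_per_octave = 16)
  sc <- morlet_cwt(ser, p)
  # closed form: zero interior points iff coi_efold * s >= T/2
  f_thresh <- sqrt(2) / 600
  excluded <- rowSums(sc$coi) == 0
  expect_true(all(sc$freqs_hz[excluded] < f_thresh))
  expect_true(all(sc$freqs_hz[!excluded] >= f_thresh * 0.999))
  # per-edge margin at 5e-3 Hz: sqrt(2)/0.005 ~ 283 s, interior ~ 634 s
  k <- which.min(abs(sc$freqs_hz - 5e-3))
  margin <- sqrt(2) / sc$freqs_hz[k]
  expect_equal(sum(sc$coi[k, ]), sum(sc$times_s >= margin &
                                       sc$times_s <= 1199 - margin))
  expect_true(abs(1199 - 2 * margin - sum(sc$coi[k, ])) < 3)
  # monotonicity: lower frequencies never admit more time than higher ones
  adm <- rowSums(sc$coi)
  expect_true(all(diff(adm) >= 0))   # freqs ascend
  # the excluded region is a contiguous prefix and suffix per row
  for (k in c(1, 40, length(sc$freqs_hz))) {
    r <- rle(sc$coi[k, ])
    expect_lte(length(r$lengths), 3)
  }
})

test_that("time-averaged amplitude peaks at the injected frequency", {
  f0 <- 0.02
  ser <- uniform_series(cos(2 * pi * f0 * (0:1199)), fs_hz = 1)
  sc <- morlet_cwt(ser, wavelet_params(0.005, 0.1, voices_per_octave = 16))
  tas <- time_average(sc)
  k <- which.max(tas$mean_amplitude)
  # within one grid step of the true frequency
  expect_lt(abs(log2(tas$freqs_hz[k] / f0)), 1 / 16 + 1e-9)
  # quadrature oracle agrees on where the peak is
  ks <- (k - 2):(k + 2)
  amp_or <- vapply(sc$freqs_hz[ks], function(f)
    Mod(cwt_quadrature(ser$values, 1, f, t = 600)), numeric(1))
  expect_equal(which.max(amp_or), 3L)
})

test_that("white-noise spectra agree between disjoint windows on average", {
  p <- wavelet_params(0.05, 0.2, voices_per_octave = 6)
  diffs <- replicate(20, {
    ser <- uniform_series(rnorm(1200), 1,
                          windows = list(w1 = c(0, 600), w2 = c(600, 1200)))
    sc <- morlet_cwt(ser, p)
    t1 <- time_average(sc, "w1"); t2 <- time_average(sc, "w2")
    mean(t1$mean_power - t2$mean_power)
  })
  # paired across seeds: no systematic difference between windows
  expect_gt(t.test(diffs)$p.value, 1e-3)
  expect_lt(abs(mean(diffs)) / 0.1, 1)
})

test_that("coi_only makes no difference where the whole row is inside the cone", {
  ser <- uniform_series(rnorm(600), 1, windows = list(mid = c(250, 350)))
  sc <- morlet_cwt(ser, wavelet_params(0.05, 0.2, 8))
  # highest frequency row: margin sqrt(2)/0.2 ~ 7 s, row inside over [250,350)
  ta1 <- time_average(sc, "mid", coi_only = TRUE)
  ta2 <- time_average(sc, "mid", coi_only = FALSE)
  k <- length(sc$freqs_hz)
  expect_equal(ta1$mean_power[k], ta2$mean_power[k], tolerance = 1e-12)
  expect_equal(ta1$mean_amplitude[k], ta2$mean_amplitude[k], tolerance = 1e-12)
})

test_that("transform guards reject Nyquist violations and bad windows", {
  ser <- uniform_series(rnorm(128), fs_hz = 1)
  expect_error(morlet_cwt(ser, wavelet_params(0.1, 0.6, 8)), "Nyquist")
  sc <- morlet_cwt(ser, wavelet_params(0.1, 0.3, 8))
  expect_error(time_average(sc, c(500, 600)), "outside")
})

test_that("scalograms and spectra export to long-form tables", {
  ser <- uniform_series(rnorm(128), 1, windows = list(w = c(20, 100)))
  sc <- morlet_cwt(ser, wavelet_params(0.05, 0.2, 6))
  d <- as.data.frame(sc)
  expect_equal(nrow(d), length(sc$freqs_hz) * 128)
  expect_named(d, c("freq_hz", "t_s", "re", "im", "in_coi"))
  expect_equal(d$re[d$freq_hz == sc$freqs_hz[2] & d$t_s == 5],
               Re(sc$coeffs[2, 6]))
  ta <- as.data.frame(time_average(sc, "w"))
  expect_equal(nrow(ta), length(sc$freqs_hz))
  w <- as.data.frame(wpco(sc, sc))
  expect_true(all(w$cphi[!is.na(w$cphi)] > 1 - 1e-12))
})
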