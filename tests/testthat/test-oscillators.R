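test_that("band catalogues hold the published mouse band edges", {
  ldf <- band_catalog("mouse_ldf")
  edges <- t(vapply(ldf, function(b) c(b$f_lo_hz, b$f_hi_hz), numeric(2)))
  expect_equal(vapply(ldf, `[[`, "", "name"),
               c("cardiac", "respiratory", "myogenic", "neurogenic",
                 "endothelial_NO", "EDHF"))
  expect_equal(edges[, 1], c(1.35, 0.15, 0.05, 0.02, 0.009, 0.005))
  expect_equal(edges[, 2], c(5, 1.35, 0.15, 0.05, 0.02, 0.009))
  met <- band_catalog("metabolic")
  expect_equal(vapply(met, `[[`, "", "name"), c("MO1", "MO2", "MO3"))
  expect_equal(vapply(met, `[[`, 1, "f_lo_hz"), c(0.005, 0.0025, 0.0015))
  # catalogue bands are non-overlapping (half-open, descending)
  for (i in seq_len(length(ldf) - 1))
    expect_lte(ldf[[i + 1]]$f_hi_hz, ldf[[i]]$f_lo_hz + 1e-12)
})

test_that("band peak frequencies recover two injected oscillators", {
  t <- (0:23999) / 20
  sig <- 1.0 * cos(2 * pi * 0.007 * t) + 0.5 * cos(2 * pi * 0.1 * t)
  sc <- morlet_cwt(uniform_series(sig, 20), wavelet_params(1.5e-3, 5, 16))
  tas <- time_average(sc)
  mt <- metrics_table(tas, band_catalog("mouse_ldf"))
  step <- 1 / 16 + 1e-9
  expect_lt(abs(log2(mt$f_peak_hz[mt$band == "EDHF"] / 0.007)), step)
  expect_lt(abs(log2(mt$f_peak_hz[mt$band == "myogenic"] / 0.1)), step)
  # the EDHF oscillator is stronger: higher relative energy than myogenic
  expect_gt(mt$E_abs[mt$band == "EDHF"] / mt$E_abs[mt$band == "myogenic"], 1)
})

test_that("relative metrics are invariant to signal scaling", {
  set.seed(21)
  v <- rnorm(1200) + cos(2 * pi * 0.02 * (0:1199))
  p <- wavelet_params(0.005, 0.1, 16)
  m1 <- metrics_table(time_average(morlet_cwt(uniform_series(v, 1), p)),
                      band_catalog("mouse_ldf")[3:6] |>
                        structure(id = "sub", class = "band_catalog"))
  m2 <- metrics_table(time_average(morlet_cwt(uniform_series(7.3 * v, 1), p)),
                      band_catalog("mouse_ldf")[3:6] |>
                        structure(id = "sub", class = "band_catalog"))
  expect_equal(m1$e_rel, m2$e_rel, tolerance = 1e-10)
  expect_equal(m1$a_rel, m2$a_rel, tolerance = 1e-10)
  expect_equal(m1$f_peak_hz, m2$f_peak_hz)
})

test_that("energy concentrated in one band maximises its density", {
  ser <- uniform_series(cos(2 * pi * 0.03 * (0:1199)), 1)
  tas <- time_average(morlet_cwt(ser, wavelet_params(0.005, 0.1, 16)))
  mt <- metrics_table(tas, band_catalog("mouse_ldf")[3:6] |>
                        structure(id = "sub", class = "band_catalog"))
  dens <- mt$e_rel          # already per-frequency densities
  expect_equal(mt$band[which.max(dens)], "neurogenic")
})

test_that("MO-2 and MO-3 are flagged unreliable on a 20-minute record", {
  ser <- uniform_series(cos(2 * pi * 0.007 * (0:1199)) + rnorm(1200, 0, 0.1), 1,
                        windows = list(baseline = c(0, 600), pe = c(600, 1200)))
  sc <- morlet_cwt(ser, wavelet_params(1.5e-3, 0.05, 16))
  for (w in list(NULL, "baseline", "pe")) {
    mt <- metrics_table(time_average(sc, w), band_catalog("metabolic"))
    expect_true(mt$reliable[mt$band == "MO1"])
    expect_false(mt$reliable[mt$band == "MO2"])
    expect_false(mt$reliable[mt$band == "MO3"])
  }
})

test_that("band_metrics errors on empty band and empty catalogue gives no rows", {
  ser <- uniform_series(rnorm(600), 1)
  tas <- time_average(morlet_cwt(ser, wavelet_params(0.05, 0.2, 8)))
  expect_error(band_metrics(tas, band("cardiac", 1.35, 5)), "cardiac")
  empty <- structure(list(), id = "none", class = "band_catalog")
  expect_equal(nrow(metrics_table(tas, empty)), 0)
})

test_that("wpco is 1 for identical signals and constant phase shifts", {
  set.seed(31)
  v <- rnorm(600) + cos(2 * pi * 0.05 * (0:599))
  p <- wavelet_params(0.02, 0.2, 8)
  sa <- morlet_cwt(uniform_series(v, 1, label = "a"), p)
  w <- wpco(sa, sa)
  expect_true(all(w$cphi[!is.na(w$cphi)] > 1 - 1e-12))
  # phase-shifted pure tone: unit coherence at every frequency
  f0 <- 0.05
  s1 <- morlet_cwt(uniform_series(cos(2 * pi * f0 * (0:599)), 1), p)
  s2 <- morlet_cwt(uniform_series(cos(2 * pi * f0 * (0:599) + 1.1), 1), p)
  w2 <- wpco(s1, s2)
  k <- which.min(abs(w2$freqs_hz - f0))
  expect_gt(w2$cphi[k], 1 - 1e-5)
  # coherence is bounded in [0, 1] for arbitrary noise pairs
  sb <- morlet_cwt(uniform_series(rnorm(600), 1, label = "b"), p)
  w3 <- wpco(sa, sb)
  ok <- !is.na(w3$cphi)
  expect_true(all(w3$cphi[ok] >= 0 & w3$cphi[ok] <= 1))
})

test_that("wpco rejects mismatched grids", {
  p1 <- wavelet_params(0.02, 0.2, 8)
  p2 <- wavelet_params(0.02, 0.2, 6)
  sa <- morlet_cwt(uniform_series(rnorm(600), 1), p1)
  sb <- morlet_cwt(uniform_series(rnorm(600), 1), p2)
  expect_error(wpco(sa, sb), "frequency grid")
  sc <- morlet_cwt(uniform_series(rnorm(500), 1), p1)
  expect_error(wpco(sa, sc), "time grid")
})

test_that("band_coherence averages the per-frequency coherence", {
  w <- structure(list(freqs_hz = c(0.005, 0.006, 0.007, 0.008),
                      cphi = rep(0.78, 4), n_times = rep(100, 4),
                      pair = "x / y", window = "all"),
                 class = "wpco_spectrum")
  bc <- band_coherence(w, band("MO1", 0.005, 0.009))
  expect_equal(bc$cphi_band, 0.78)
  expect_error(band_coherence(w, band("MO2", 0.0025, 0.005)), "MO2")
  w$cphi <- rep(NA_real_, 4)
  expect_error(band_coherence(w, band("MO1", 0.005, 0.009)), "admissible")
})

test_that("raising an oscillator's amplitude raises its band energy density", {
  # EDHF oscillator of varying amplitude against a fixed myogenic
  # oscillator and fixed noise (paired seeds), so the total spectrum is
  # not dominated by the varying component
  p <- wavelet_params(0.005, 0.2, 12)
  edhf <- band("EDHF", 0.005, 0.009)
  e_rel_for <- function(amp, seed) {
    set.seed(seed)
    a <- generate_oscillator_series(1200, 1, 0.007, amplitude = amp, snr = Inf)
    b <- generate_oscillator_series(1200, 1, 0.1, amplitude = 2, snr = Inf)
    noise <- rnorm(1200, 0, 0.7)
    ser <- uniform_series(a$series$values + b$series$values + noise, 1)
    band_metrics(time_average(morlet_cwt(ser, p)), edhf)$e_rel
  }
  lo <- vapply(1:20, function(s) e_rel_for(1.0, s), numeric(1))
  hi <- vapply(1:20, function(s) e_rel_for(2.0, s), numeric(1))
  expect_gt(median(hi), median(lo))
  expect_gt(mean(hi > lo), 0.8)   # paired: nearly always increases
})
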