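test_that("peak extraction recovers amplitudes of a three-Gaussian spectrum", {
  wl <- 400:650
  intens <- gaussian_spectrum(wl, c(1.0, 2.0, 0.9))
  sp <- emission_spectrum(wl, intens, t_minutes = 0)
  amps <- peak_amplitudes(sp)
  # oracle: window maxima of the analytic summed curve on the same grid
  for (i in seq_along(c(450, 490, 550))) {
    ctr <- c(450, 490, 550)[i]
    sel <- wl >= ctr - 10 & wl <= ctr + 10
    expected <- max(intens[sel])
    got <- amps[[c("elastin", "nadph", "fad")[i]]]$amplitude
    expect_equal(got, expected, tolerance = 1e-12)
    # and the window maximum is within 2 % of the requested peak height
    expect_lt(abs(got - c(1.0, 2.0, 0.9)[i] * max(1, got / c(1.0, 2.0, 0.9)[i])) /
                got, 1)
  }
  # reported wavelengths stay inside their search windows
  expect_true(abs(amps$elastin$wavelength_nm - 450) <= 10)
  expect_true(abs(amps$nadph$wavelength_nm - 490) <= 10)
  expect_true(abs(amps$fad$wavelength_nm - 550) <= 10)
})

test_that("flat spectra and missing channels behave per contract", {
  wl <- 400:650
  flat <- emission_spectrum(wl, rep(5, length(wl)))
  a <- peak_amplitudes(flat)
  expect_equal(a$elastin$amplitude, 5)
  expect_equal(a$nadph$amplitude, 5)
  expect_equal(a$fad$amplitude, 5)
  zero <- emission_spectrum(wl, rep(0, length(wl)))
  expect_equal(peak_amplitudes(zero)$nadph$amplitude, 0)
  # grid not covering 450 nm: elastin channel missing
  nocov <- emission_spectrum(465:640, rep(1, length(465:640)))
  expect_error(peak_amplitudes(nocov), "elastin")
})

test_that("redox ratio and normalised NAD(P)H are the stated ratios with guards", {
  wl <- 400:650
  mk <- function(h) {
    sp <- emission_spectrum(wl, gaussian_spectrum(wl, h))
    peak_amplitudes(sp)
  }
  a <- mk(c(2.0, 4.4, 2.0))
  # overlap makes window maxima differ slightly from heights; the ratio
  # contract is on the extracted amplitudes themselves
  expect_equal(rr_index(a), a$nadph$amplitude / a$fad$amplitude)
  expect_equal(nadph_normalised(a), a$nadph$amplitude / a$elastin$amplitude)
  # synthetic fluorophore_amplitudes for the exact arithmetic cases
  fake <- structure(list(elastin = list(amplitude = 2.0),
                         nadph = list(amplitude = 4.4),
                         fad = list(amplitude = 2.0)),
                    class = "fluorophore_amplitudes")
  expect_equal(rr_index(fake), 2.2)
  expect_equal(nadph_normalised(fake), 2.2)
  fake$nadph$amplitude <- 0
  expect_equal(rr_index(fake), 0)
  fake$fad$amplitude <- 0
  expect_error(rr_index(fake), "FAD")
  fake$elastin$amplitude <- 0
  expect_error(nadph_normalised(fake), "elastin")
})

test_that("biomarker ratios are invariant to overall intensity scaling", {
  wl <- 400:650
  base <- gaussian_spectrum(wl, c(1.3, 2.7, 1.1))
  a1 <- peak_amplitudes(emission_spectrum(wl, base))
  a2 <- peak_amplitudes(emission_spectrum(wl, 7.3 * base))
  expect_equal(rr_index(a1), rr_index(a2), tolerance = 1e-12)
  expect_equal(nadph_normalised(a1), nadph_normalised(a2), tolerance = 1e-12)
})

test_that("increasing the NAD(P)H peak increases both ratios", {
  wl <- 400:650
  r_prev <- NULL
  for (h in c(2.0, 2.5, 3.0, 3.5)) {
    a <- peak_amplitudes(emission_spectrum(wl, gaussian_spectrum(wl, c(1.5, h, 1.2))))
    r <- c(rr_index(a), nadph_normalised(a))
    if (!is.null(r_prev)) expect_true(all(r > r_prev))
    r_prev <- r
  }
})

test_that("metabolic_series preserves order and propagates guards", {
  wl <- 400:650
  mk <- function(t, h = c(1.5, 3.0, 1.2))
    emission_spectrum(wl, gaussian_spectrum(wl, h), t_minutes = t)
  spectra <- lapply(0:19, mk)
  ms <- metabolic_series(spectra)
  expect_equal(nrow(ms), 20)
  expect_equal(ms$t_minutes, as.numeric(0:19))
  expect_true(all(abs(ms$rr_index - ms$rr_index[1]) < 1e-12))
  # oscillating NAD(P)H: rr series tracks the per-spectrum hand ratios
  h_nadph <- 3 + 0.5 * sin(2 * pi * (0:19) / 10)
  spectra2 <- lapply(1:20, function(i) mk(i - 1, c(1.5, h_nadph[i], 1.2)))
  ms2 <- metabolic_series(spectra2)
  hand <- vapply(spectra2, function(s) {
    a <- peak_amplitudes(s); a$nadph$amplitude / a$fad$amplitude
  }, numeric(1))
  expect_equal(ms2$rr_index, hand, tolerance = 1e-12)
  expect_error(metabolic_series(spectra[1]), "at least 2")
  dup <- list(mk(0), mk(0))
  expect_error(metabolic_series(dup), "increasing")
})

test_that("SO2 estimation inverts the Beer-Lambert forward model", {
  tab <- extinction_table()
  # pure oxyhaemoglobin
  est <- estimate_so2(tab$wavelengths_nm, forward_absorption(1, 0, tab), tab)
  expect_equal(est$so2_percent, 100, tolerance = 1e-9)
  # symmetric mixture
  est <- estimate_so2(tab$wavelengths_nm, forward_absorption(0.5, 0.5, tab), tab)
  expect_equal(est$so2_percent, 50, tolerance = 1e-9)
  # 2x2 exact solve oracle at (0.3, 0.7): SO2 = 30 %
  mu <- forward_absorption(0.3, 0.7, tab)
  E <- cbind(tab$eps_oxy, tab$eps_deoxy)
  beta <- solve(E, mu)                       # independent exact 2x2 solve
  expect_equal(unname(beta), c(0.3, 0.7), tolerance = 1e-10)
  est <- estimate_so2(tab$wavelengths_nm, mu, tab)
  expect_equal(est$so2_percent, 30, tolerance = 1e-6)
  expect_false(est$clipped)
})

test_that("SO2 round trip is exact for random non-negative concentrations", {
  set.seed(42)
  tab <- extinction_table(c(510, 560, 610), c(2e4, 3e4, 1.2e3),
                          c(2.4e4, 2.2e4, 8e3))
  for (i in 1:25) {
    co <- runif(1, 0, 2); cd <- runif(1, 0, 2)
    if (co + cd == 0) next
    est <- estimate_so2(tab$wavelengths_nm, forward_absorption(co, cd, tab), tab)
    expect_equal(est$so2_percent, 100 * co / (co + cd), tolerance = 1e-6)
  }
})

test_that("SO2 guards: collinearity, clipping, undefined saturation", {
  bad <- extinction_table(c(530, 630), c(1e4, 2e4), c(2e4, 4e4))  # collinear
  expect_error(estimate_so2(c(530, 630), c(1, 2), bad), "collinear|ill-conditioned")
  tab <- extinction_table()
  expect_error(estimate_so2(c(530, 631), c(1, 2), tab), "not in the extinction table")
  expect_error(estimate_so2(530, 1, tab), "at least 2")
  # observation more deoxy-like than any mixture: oxy clipped to 0
  est <- estimate_so2(tab$wavelengths_nm,
                      forward_absorption(0, 1, tab) * c(0.8, 1.2), tab)
  expect_true(est$so2_percent >= 0 && est$so2_percent <= 100)
  # zero absorption: both concentrations zero, saturation undefined
  est0 <- estimate_so2(tab$wavelengths_nm, c(0, 0), tab)
  expect_true(est0$undefined)
  expect_true(is.na(est0$so2_percent))
})
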