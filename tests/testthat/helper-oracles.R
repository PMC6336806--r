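# Independent oracles used across the suite.

# Direct quadrature of the continuous wavelet integral
#   W(s, t) = s^(-1/2) * sum_u psi((u - t)/s) g(u) du
# with the analytic Morlet psi(u) = pi^(-1/4) exp(i 2 pi f0 u) exp(-u^2/2).
# Deliberately shares no code with the package's FFT path.
cwt_quadrature <- function(values, fs, freq, t, f0 = 1) {
  s <- f0 / freq
  u <- (seq_along(values) - 1) / fs
  g <- values - mean(values)
  psi <- pi^(-0.25) * exp(1i * 2 * pi * f0 * (u - t) / s) *
    exp(-((u - t) / s)^2 / 2)
  sum(psi * g) / fs / sqrt(s)
}

# Natural-spline second-derivative system solved directly (tridiagonal),
# evaluated piecewise; oracle for the reconstruction module.
natural_spline_oracle <- function(x, y, xi) {
  n <- length(x)
  h <- diff(x)
  A <- matrix(0, n, n); b <- numeric(n)
  A[1, 1] <- 1; A[n, n] <- 1           # natural: M1 = Mn = 0
  for (i in 2:(n - 1)) {
    A[i, i - 1] <- h[i - 1] / 6
    A[i, i] <- (h[i - 1] + h[i]) / 3
    A[i, i + 1] <- h[i] / 6
    b[i] <- (y[i + 1] - y[i]) / h[i] - (y[i] - y[i - 1]) / h[i - 1]
  }
  M <- solve(A, b)
  k <- pmin(pmax(findInterval(xi, x), 1), n - 1)
  hk <- h[k]; dl <- x[k + 1] - xi; dr <- xi - x[k]
  (M[k] * dl^3 + M[k + 1] * dr^3) / (6 * hk) +
    (y[k] / hk - M[k] * hk / 6) * dl + (y[k + 1] / hk - M[k + 1] * hk / 6) * dr
}

# Three-Gaussian emission model used by the spectral fixtures
gaussian_spectrum <- function(wl, heights, centres = c(450, 490, 550),
                              sigma = 15) {
  rowSums(sapply(seq_along(heights), function(i)
    heights[i] * exp(-(wl - centres[i])^2 / (2 * sigma^2))))
}

# Reference values computed once with an independent implementation
# (scipy.stats 1.17: shapiro, pearsonr) and frozen.
REF_SHAPIRO_SMALL_W <- 0.9992933591693641    # x = c(2.1, 2.2, 2.0, 2.3, 2.15)
REF_SHAPIRO_SMALL_P <- 0.9998029362346917
REF_SHAPIRO_BIMODAL_P <- 8.099750290870789e-06  # ten 0s, ten 10s
REF_PEARSON_R <- 0.8219949365267865          # x = 1:5, y = c(2,1,4,3,6)
REF_PEARSON_P <- 0.08770664700806553
# scipy.interpolate.CubicSpline(..., bc_type='not-a-knot') on the fixture
# below, evaluated at REF_NAK_XI
REF_NAK_X <- c(0, 55, 130, 190, 260, 330)
REF_NAK_Y <- c(1.2, 3.4, 2.8, 5.5, 4.1, 4.9)
REF_NAK_XI <- c(10, 70, 100, 150, 225, 300)
REF_NAK_VALUES <- c(2.1153791967, 3.2048781167, 2.6653981621,
                    3.6415155826, 5.2940963692, 3.4984783617)
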