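#' Morlet wavelet analysis parameters
#'
#' The analysing wavelet is the (analytic) Morlet wavelet
#' `psi(u) = pi^(-1/4) * exp(i * 2*pi*f0 * u) * exp(-u^2 / 2)` with cyclic
#' central frequency `f0` (default 1), so that a scale `s` corresponds to
#' the frequency `f = f0 / s`. Frequencies are analysed on a logarithmic
#' grid with a fixed number of voices per octave.
#'
#' @param f_min_hz,f_max_hz analysed frequency range (Hz).
#' @param voices_per_octave grid density (integer >= 4, default 16).
#' @param central_frequency Morlet centre frequency in cycles (default 1).
#' @param coi_efold e-folding factor of the cone of influence: a point is
#'   inside the cone when its distance from both record edges is at least
#'   `coi_efold * s`. Default `sqrt(2)`, the Morlet amplitude e-folding time.
#' @return object of class `wavelet_params`.
#' @export
wavelet_params <- function(f_min_hz, f_max_hz, voices_per_octave = 16L,
                           central_frequency = 1, coi_efold = sqrt(2)) {
  if (!is.numeric(f_min_hz) || !is.numeric(f_max_hz) ||
      f_min_hz <= 0 || f_max_hz <= f_min_hz)
    stop("need 0 < f_min_hz < f_max_hz")
  voices_per_octave <- as.integer(voices_per_octave)
  if (voices_per_octave < 4L) stop("voices_per_octave must be >= 4")
  if (central_frequency <= 0) stop("central_frequency must be positive")
  structure(list(f_min_hz = f_min_hz, f_max_hz = f_max_hz,
                 voices_per_octave = voices_per_octave,
                 central_frequency = central_frequency,
                 coi_efold = coi_efold),
            class = "wavelet_params")
}

#' Logarithmic frequency grid of a parameter set
#'
#' Ascending grid `f_max * 2^(-k / voices)` for integer `k >= 0` down to
#' `f_min` (always including `f_max`, and `f_min` when it falls on the
#' grid).
#'
#' @param params a [wavelet_params()].
#' @return ascending numeric vector of frequencies (Hz).
#' @export
frequency_grid <- function(params) {
  stopifnot(inherits(params, "wavelet_params"))
  n_oct <- log2(params$f_max_hz / params$f_min_hz)
  k <- 0:floor(n_oct * params$voices_per_octave + 1e-9)
  rev(params$f_max_hz * 2^(-k / params$voices_per_octave))
}

#' Morlet continuous wavelet transform
#'
#' Computes `W(s, t) = s^(-1/2) * integral psi((u - t)/s) g(u) du` for every
#' scale on the logarithmic frequency grid, by FFT convolution (the signal
#' is zero-padded to the next power of two at least twice the record
#' length, so circular wrap-around is negligible inside the cone of
#' influence). The record mean is removed
#' before the transform to avoid a spurious zero-frequency ridge.
#'
#' @param series a [uniform_series()].
#' @param params a [wavelet_params()] with `f_max_hz` at or below the
#'   Nyquist frequency.
#' @return object of class `scalogram`: list with ascending `freqs_hz`,
#'   `times_s`, complex coefficient matrix `coeffs` (frequency x time),
#'   logical `coi` of the same shape (`TRUE` inside the cone of influence),
#'   the `params`, sampling rate `fs_hz`, window list and `label` inherited
#'   from the series.
#' @export
morlet_cwt <- function(series, params) {
  stopifnot(inherits(series, "uniform_series"),
            inherits(params, "wavelet_params"))
  g <- series$values
  if (any(!is.finite(g))) stop("signal contains non-finite samples")
  fs <- series$fs_hz
  if (params$f_max_hz > fs / 2 + 1e-12)
    stop(sprintf("f_max_hz (%g) exceeds the Nyquist frequency (%g)",
                 params$f_max_hz, fs / 2))
  n <- length(g)
  g <- g - mean(g)
  n2 <- 2^ceiling(log2(2 * n))  # >= 2n so wrap-around stays negligible
  G <- stats::fft(c(g, rep(0, n2 - n)))
  # angular FFT bin frequencies
  j <- 0:(n2 - 1)
  omega <- 2 * pi * ifelse(j <= n2 / 2, j, j - n2) * fs / n2
  freqs <- frequency_grid(params)
  f0 <- params$central_frequency
  W <- matrix(0i, nrow = length(freqs), ncol = n)
  for (k in seq_along(freqs)) {
    s <- f0 / freqs[k]
    # Fourier transform of u -> psi(-(u)/s), evaluated on the bin grid:
    # peaks at omega = -2*pi*f0/s, i.e. the transform responds on the
    # negative-frequency side (the integral uses psi, not its conjugate)
    psi_hat <- pi^(-0.25) * sqrt(2 * pi) * exp(-(s * omega + 2 * pi * f0)^2 / 2)
    W[k, ] <- sqrt(s) * stats::fft(G * psi_hat, inverse = TRUE)[1:n] / n2
  }
  times <- series_times(series)
  out <- structure(list(freqs_hz = freqs, times_s = times, coeffs = W,
                        coi = NULL, params = params, fs_hz = fs,
                        windows = series$windows, label = series$label),
                   class = "scalogram")
  out$coi <- compute_coi(out)
  out
}

#' Cone-of-influence mask of a scalogram
#'
#' A time-frequency point is inside the cone of influence when its distance
#' from both edges of the record is at least `coi_efold * s`, where
#' `s = central_frequency / f` is the scale. Outside the cone, coefficients
#' are contaminated by the finite record length (boundary effects) and are
#' excluded from time averages by default. The mask is monotone: lower
#' frequencies exclude at least as much time as higher ones.
#'
#' @param scalogram a `scalogram` (the mask is recomputed, not read).
#' @param coi_efold e-folding factor; default taken from the scalogram's
#'   parameters.
#' @return logical matrix (frequency x time), `TRUE` inside the cone.
#' @export
compute_coi <- function(scalogram, coi_efold = scalogram$params$coi_efold) {
  stopifnot(inherits(scalogram, "scalogram"))
  tt <- scalogram$times_s
  t_lo <- tt[1]
  t_hi <- tt[length(tt)]
  margin <- coi_efold * scalogram$params$central_frequency / scalogram$freqs_hz
  M <- matrix(tt, nrow = length(margin), ncol = length(tt), byrow = TRUE)
  (M - t_lo >= margin) & (t_hi - M >= margin)
}

#' @export
print.scalogram <- function(x, ...) {
  cat(sprintf("<scalogram> '%s': %d frequencies [%.4g, %.4g] Hz x %d times, %d voices/octave\n",
              x$label, length(x$freqs_hz), min(x$freqs_hz), max(x$freqs_hz),
              length(x$times_s), x$params$voices_per_octave))
  cat(sprintf("  %.1f%% of points inside the cone of influence\n",
              100 * mean(x$coi)))
  invisible(x)
}

#' @export
plot.scalogram <- function(x, power = TRUE, ...) {
  z <- Mod(x$coeffs)
  if (power) z <- z^2
  z[!x$coi] <- NA
  graphics::image(x$times_s, log10(x$freqs_hz), t(z),
                  xlab = "time (s)", ylab = "log10 frequency (Hz)",
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE), ...)
  invisible(x)
}

#' Time-averaged wavelet spectrum
#'
#' Averages the wavelet power `|W|^2` and amplitude `|W|` over time, per
#' frequency, within an analysis window, by default restricted to points
#' inside the cone of influence. Frequencies with no admissible time points
#' are flagged unreliable (`NaN` means, `reliable = FALSE`) rather than
#' dropped.
#'
#' @param scalogram a `scalogram`.
#' @param window `NULL` for the whole record, the name of a window attached
#'   to the source series, or a `c(start_s, end_s)` half-open interval.
#' @param coi_only if `TRUE` (default) only points inside the cone of
#'   influence enter the averages.
#' @return object of class `tavg_spectrum`: data-frame-like list with
#'   `freqs_hz`, `mean_power`, `mean_amplitude`, `n_times` (admissible
#'   points per frequency), `coverage` (admissible fraction of the window
#'   span per frequency), `reliable`, and the window label.
#' @export
time_average <- function(scalogram, window = NULL, coi_only = TRUE) {
  stopifnot(inherits(scalogram, "scalogram"))
  tt <- scalogram$times_s
  if (is.null(window)) {
    sel_t <- rep(TRUE, length(tt))
    wlab <- "all"
  } else {
    if (is.character(window)) {
      wlab <- window
      if (is.null(scalogram$windows[[window]]))
        stop(sprintf("no window named '%s' on this scalogram", window))
      window <- scalogram$windows[[window]]
    } else wlab <- sprintf("[%g,%g)", window[1], window[2])
    if (window[1] > tt[length(tt)] || window[2] < tt[1])
      stop("window lies outside the record")
    sel_t <- tt >= window[1] & tt < window[2]
  }
  adm <- matrix(sel_t, nrow = length(scalogram$freqs_hz),
                ncol = length(tt), byrow = TRUE)
  if (coi_only) adm <- adm & scalogram$coi
  n_adm <- rowSums(adm)
  if (all(n_adm == 0))
    stop("window is outside the cone of influence at every frequency")
  P <- Mod(scalogram$coeffs)^2
  A <- Mod(scalogram$coeffs)
  mp <- rowSums(P * adm) / n_adm  # NaN where n_adm == 0
  ma <- rowSums(A * adm) / n_adm
  structure(list(freqs_hz = scalogram$freqs_hz, mean_power = mp,
                 mean_amplitude = ma, n_times = n_adm,
                 coverage = n_adm / max(sum(sel_t), 1L),
                 reliable = n_adm > 0, window = wlab,
                 label = scalogram$label,
                 voices_per_octave = scalogram$params$voices_per_octave),
            class = "tavg_spectrum")
}

#' @export
print.tavg_spectrum <- function(x, ...) {
  cat(sprintf("<tavg_spectrum> '%s', window %s: %d frequencies [%.4g, %.4g] Hz (%d unreliable)\n",
              x$label, x$window, length(x$freqs_hz), min(x$freqs_hz),
              max(x$freqs_hz), sum(!x$reliable)))
  invisible(x)
}

#' @export
plot.tavg_spectrum <- function(x, power = TRUE, ...) {
  y <- if (power) x$mean_power else x$mean_amplitude
  graphics::plot(x$freqs_hz, y, type = "l", log = "x",
                 xlab = "frequency (Hz)",
                 ylab = if (power) "mean wavelet power" else "mean wavelet amplitude",
                 ...)
  invisible(x)
}

#' @export
as.data.frame.scalogram <- function(x, ...) {
  # long form: one row per (frequency, time) point
  data.frame(freq_hz = rep(x$freqs_hz, times = length(x$times_s)),
             t_s = rep(x$times_s, each = length(x$freqs_hz)),
             re = as.vector(Re(x$coeffs)),
             im = as.vector(Im(x$coeffs)),
             in_coi = as.vector(x$coi))
}

#' @export
as.data.frame.tavg_spectrum <- function(x, ...) {
  data.frame(freq_hz = x$freqs_hz, mean_power = x$mean_power,
             mean_amplitude = x$mean_amplitude, n_times = x$n_times,
             coverage = x$coverage, reliable = x$reliable,
             window = x$window, signal = x$label)
}
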