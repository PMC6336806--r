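#' Irregularly sampled signal
#'
#' @param t_seconds strictly increasing sample times (s).
#' @param values finite sample values.
#' @param label signal name.
#' @return object of class `irregular_series`.
#' @export
irregular_series <- function(t_seconds, values, label = "signal") {
  t_seconds <- as.numeric(t_seconds)
  values <- as.numeric(values)
  if (length(t_seconds) != length(values)) stop("time and value lengths differ")
  if (any(diff(t_seconds) <= 0)) stop("sample times must be strictly increasing")
  if (any(!is.finite(values))) stop("values must be finite")
  structure(list(t_seconds = t_seconds, values = values, label = label),
            class = "irregular_series")
}

#' Uniformly sampled signal
#'
#' Evenly sampled signal (an LDF perfusion trace or a reconstructed
#' biomarker trace) with an optional set of named, non-overlapping,
#' half-open analysis windows such as `baseline = c(0, 600)` and
#' `pe = c(600, 1200)`.
#'
#' @param values finite sample values.
#' @param fs_hz sampling rate (Hz).
#' @param t0_seconds time of the first sample (s).
#' @param label signal name.
#' @param windows named list of `c(start_s, end_s)` half-open intervals.
#' @return object of class `uniform_series`.
#' @export
uniform_series <- function(values, fs_hz, t0_seconds = 0, label = "signal",
                           windows = list()) {
  values <- as.numeric(values)
  if (any(!is.finite(values))) stop("values must be finite")
  if (!is.numeric(fs_hz) || fs_hz <= 0) stop("fs_hz must be positive")
  x <- structure(list(values = values, fs_hz = fs_hz,
                      t0_seconds = as.numeric(t0_seconds), label = label,
                      windows = list()),
                 class = "uniform_series")
  if (length(windows)) x <- segment(x, windows) else x
}

#' Sample times of a uniform series
#' @param x a [uniform_series()].
#' @return numeric vector of sample times (s).
#' @export
series_times <- function(x) {
  stopifnot(inherits(x, "uniform_series"))
  x$t0_seconds + (seq_along(x$values) - 1L) / x$fs_hz
}

#' @export
print.uniform_series <- function(x, ...) {
  tt <- series_times(x)
  cat(sprintf("<uniform_series> '%s': %d samples at %g Hz, t = [%g, %g] s\n",
              x$label, length(x$values), x$fs_hz, tt[1], tt[length(tt)]))
  if (length(x$windows))
    for (nm in names(x$windows))
      cat(sprintf("  window %-10s [%g, %g) s\n", nm,
                  x$windows[[nm]][1], x$windows[[nm]][2]))
  invisible(x)
}

#' @export
plot.uniform_series <- function(x, ...) {
  graphics::plot(series_times(x), x$values, type = "l",
                 xlab = "time (s)", ylab = x$label, ...)
  if (length(x$windows))
    graphics::abline(v = unique(unlist(x$windows)), lty = 3, col = "grey40")
  invisible(x)
}

#' Attach named analysis windows to a uniform series
#'
#' Labels half-open time intervals (e.g. baseline vs. stimulus) on the
#' series without copying or altering samples. Windows must lie within the
#' record and must not overlap each other.
#'
#' @param series a [uniform_series()].
#' @param windows named list of `c(start_s, end_s)` intervals; an empty list
#'   leaves the series unchanged.
#' @return the series with windows attached.
#' @export
segment <- function(series, windows) {
  stopifnot(inherits(series, "uniform_series"))
  if (!length(windows)) return(series)
  if (is.null(names(windows)) || any(names(windows) == ""))
    stop("windows must be named")
  tt <- series_times(series)
  t_end <- tt[length(tt)] + 1 / series$fs_hz  # half-open record extent
  for (nm in names(windows)) {
    w <- as.numeric(windows[[nm]])
    if (length(w) != 2L || w[1] >= w[2])
      stop(sprintf("window '%s' must be c(start, end) with start < end", nm))
    if (w[1] < tt[1] || w[2] > t_end + 1e-9)
      stop(sprintf("window '%s' [%g, %g) lies outside the record [%g, %g)",
                   nm, w[1], w[2], tt[1], t_end))
  }
  ord <- order(vapply(windows, `[`, numeric(1), 1L))
  ws <- windows[ord]
  for (i in seq_len(length(ws) - 1L))
    if (ws[[i]][2] > ws[[i + 1L]][1] + 1e-9)
      stop(sprintf("windows '%s' and '%s' overlap",
                   names(ws)[i], names(ws)[i + 1L]))
  series$windows <- lapply(ws, as.numeric)
  series
}

#' Reconstruct a uniform signal by piecewise cubic spline interpolation
#'
#' Interpolates discrete biomarker samples (e.g. one redox-ratio value per
#' minute) onto a uniform grid so that continuous wavelet analysis can be
#' applied. The interpolant passes through every knot exactly and is never
#' extrapolated: the output grid is `t_min + k / fs_hz` restricted to the
#' knot span.
#'
#' The default boundary condition is not-a-knot (the first two and last two
#' polynomial pieces coincide), which behaves better than a natural spline
#' at the ends of short 20-point records; a natural spline (zero second
#' derivative at the ends) is available as an option.
#'
#' @param series an [irregular_series()] with at least 4 knots.
#' @param fs_hz target sampling rate (Hz); default 1.
#' @param boundary `"not-a-knot"` (default) or `"natural"`.
#' @param windows optional named windows to attach to the result.
#' @return a [uniform_series()].
#' @export
spline_reconstruct <- function(series, fs_hz = 1,
                               boundary = c("not-a-knot", "natural"),
                               windows = list()) {
  stopifnot(inherits(series, "irregular_series"))
  boundary <- match.arg(boundary)
  x <- series$t_seconds
  y <- series$values
  if (length(x) < 4L) stop("cubic reconstruction needs at least 4 knots")
  t_out <- x[1] + seq(0, floor((x[length(x)] - x[1]) * fs_hz)) / fs_hz
  vals <- switch(boundary,
    "natural" = stats::spline(x, y, xout = t_out, method = "natural")$y,
    "not-a-knot" = spline_nak(x, y, t_out))
  uniform_series(vals, fs_hz = fs_hz, t0_seconds = x[1],
                 label = series$label, windows = windows)
}

# Not-a-knot cubic spline evaluated at xi (no extrapolation checks here;
# callers keep xi inside [x1, xn]). Solves for the knot second derivatives
# M with continuity of the third derivative across the second and the
# penultimate knot, then evaluates the standard piecewise cubic form.
spline_nak <- function(x, y, xi) {
  n <- length(x)
  h <- diff(x)
  A <- matrix(0, n, n)
  b <- numeric(n)
  for (i in 2:(n - 1)) {
    A[i, i - 1] <- h[i - 1] / 6
    A[i, i]     <- (h[i - 1] + h[i]) / 3
    A[i, i + 1] <- h[i] / 6
    b[i] <- (y[i + 1] - y[i]) / h[i] - (y[i] - y[i - 1]) / h[i - 1]
  }
  # not-a-knot: S''' continuous at x2 and x[n-1]
  A[1, 1:3] <- c(h[2], -(h[1] + h[2]), h[1])
  A[n, (n - 2):n] <- c(h[n - 1], -(h[n - 2] + h[n - 1]), h[n - 2])
  M <- solve(A, b)
  k <- pmin(pmax(findInterval(xi, x), 1L), n - 1L)
  hk <- h[k]
  dl <- x[k + 1L] - xi
  dr <- xi - x[k]
  (M[k] * dl^3 + M[k + 1L] * dr^3) / (6 * hk) +
    (y[k] / hk - M[k] * hk / 6) * dl +
    (y[k + 1L] / hk - M[k + 1L] * hk / 6) * dr
}

#' Anti-aliased decimation of a uniform series
#'
#' Low-pass filters and downsamples by an integer factor (useful to reduce a
#' 20 Hz LDF record before low-frequency wavelet analysis; every analysed
#' vasomotion band lies well below 1 Hz). Large factors are applied in
#' stages to keep the anti-aliasing filter well behaved.
#'
#' @param series a [uniform_series()].
#' @param factor integer decimation factor (>= 2).
#' @return a [uniform_series()] at `fs_hz / factor`, windows preserved.
#' @export
decimate_series <- function(series, factor) {
  stopifnot(inherits(series, "uniform_series"))
  factor <- as.integer(factor)
  if (factor < 2L) stop("decimation factor must be >= 2")
  stages <- integer(0)
  f <- factor
  while (f > 8L) {
    for (d in c(8L, 7L, 6L, 5L, 4L, 3L, 2L)) if (f %% d == 0L) break
    if (f %% d != 0L) stop("decimation factor must factor into stages <= 8")
    stages <- c(stages, d); f <- f %/% d
  }
  if (f > 1L) stages <- c(stages, f)
  v <- series$values
  for (d in stages) v <- signal::decimate(v, d, ftype = "iir")
  out <- uniform_series(v, fs_hz = series$fs_hz / factor,
                        t0_seconds = series$t0_seconds, label = series$label)
  out$windows <- series$windows
  out
}
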