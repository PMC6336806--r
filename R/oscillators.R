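#' Physiological frequency band
#'
#' Half-open frequency interval `[f_lo, f_hi)` naming one physiological
#' oscillator. Half-open intervals prevent double counting at shared
#' boundaries (e.g. 9e-3 Hz belongs to the endothelial NO band, not EDHF).
#'
#' @param name band name.
#' @param f_lo_hz,f_hi_hz band edges (Hz), `0 < f_lo < f_hi`.
#' @return object of class `osc_band`.
#' @export
band <- function(name, f_lo_hz, f_hi_hz) {
  if (!(f_lo_hz > 0 && f_hi_hz > f_lo_hz)) stop("need 0 < f_lo < f_hi")
  structure(list(name = name, f_lo_hz = f_lo_hz, f_hi_hz = f_hi_hz),
            class = "osc_band")
}

#' Band catalogues for mouse skin recordings
#'
#' `"mouse_ldf"` holds the six vasomotion bands of the mouse LDF perfusion
#' signal: cardiac 1.35-5 Hz, respiratory 0.15-1.35 Hz, myogenic
#' 0.05-0.15 Hz, neurogenic 0.02-0.05 Hz, endothelial NO-dependent
#' 0.009-0.02 Hz and endothelial NO-independent (EDHF) 0.005-0.009 Hz.
#' `"metabolic"` holds the three slow metabolic-oscillator bands of the
#' reconstructed autofluorescence biomarkers: MO-1 0.005-0.009 Hz, MO-2
#' 0.0025-0.005 Hz and MO-3 0.0015-0.0025 Hz.
#'
#' @param id `"mouse_ldf"` or `"metabolic"`.
#' @return list of [band()]s (class `band_catalog`), highest-frequency band
#'   first.
#' @export
band_catalog <- function(id = c("mouse_ldf", "metabolic")) {
  id <- match.arg(id)
  bands <- switch(id,
    mouse_ldf = list(
      band("cardiac",        1.35,  5),
      band("respiratory",    0.15,  1.35),
      band("myogenic",       0.05,  0.15),
      band("neurogenic",     0.02,  0.05),
      band("endothelial_NO", 0.009, 0.02),
      band("EDHF",           0.005, 0.009)),
    metabolic = list(
      band("MO1", 0.005,  0.009),
      band("MO2", 0.0025, 0.005),
      band("MO3", 0.0015, 0.0025)))
  structure(bands, id = id, class = "band_catalog")
}

#' @export
print.band_catalog <- function(x, ...) {
  cat(sprintf("<band_catalog> '%s'\n", attr(x, "id")))
  for (b in x)
    cat(sprintf("  %-15s [%g, %g) Hz\n", b$name, b$f_lo_hz, b$f_hi_hz))
  invisible(x)
}

#' Band summary of a time-averaged wavelet spectrum
#'
#' Summarises one oscillator band by its absolute and relative wavelet
#' energy and amplitude and the frequency of its spectral peak. The
#' absolute energy `E_i` is the trapezoidal integral of the mean wavelet
#' power over the band's grid frequencies (area under the curve, in linear
#' frequency); the relative energy is `e_i = E_i / (E_tot * n_i)` where
#' `E_tot` is the same integral over the whole analysed grid and `n_i` the
#' number of grid frequencies in the band. The absolute amplitude `A_i` is
#' the maximum mean wavelet amplitude in the band and
#' `a_i = A_i / (A_tot * n_i)` with `A_tot` the global maximum. `f` is the
#' grid frequency at which the band's mean amplitude peaks.
#'
#' Because `n_i` counts log-grid frequencies, relative metrics depend on
#' the grid density; the grid's voices-per-octave is carried on every
#' result so metrics are only ever compared across equal grids.
#'
#' A band is flagged `reliable = FALSE` when any of its grid frequencies
#' has boundary-contaminated coefficients over more than half of the
#' averaging span (cone-of-influence coverage below `min_coverage`). For a
#' 20-minute record this reproduces the usual practice of interpreting
#' only the fastest metabolic band (MO-1) and discarding MO-2/MO-3, whose
#' time courses fall largely outside the cone.
#'
#' @param tas a [time_average()] spectrum.
#' @param bd an [band()].
#' @param energy `"trapezoid"` (default) integrates mean power over linear
#'   frequency; `"sum"` adds the grid values instead.
#' @param min_coverage minimum admissible fraction of the averaging span
#'   required at every band frequency for the band to count as reliable.
#' @return one-row data frame: `band`, `E_abs`, `e_rel`, `A_abs`, `a_rel`,
#'   `f_peak_hz`, `n_freqs`, `reliable`, `voices_per_octave`.
#' @export
band_metrics <- function(tas, bd, energy = c("trapezoid", "sum"),
                         min_coverage = 0.5) {
  stopifnot(inherits(tas, "tavg_spectrum"), inherits(bd, "osc_band"))
  energy <- match.arg(energy)
  f <- tas$freqs_hz
  sel <- f >= bd$f_lo_hz & f < bd$f_hi_hz
  if (!any(sel))
    stop(sprintf("band '%s' contains no grid frequencies", bd$name))
  integ <- function(fx, y) {
    ok <- is.finite(y)
    fx <- fx[ok]; y <- y[ok]
    if (length(y) == 0L) return(NA_real_)
    if (length(y) == 1L) return(y)
    if (energy == "sum") return(sum(y))
    sum(diff(fx) * (y[-1] + y[-length(y)]) / 2)
  }
  E_abs <- integ(f[sel], tas$mean_power[sel])
  E_tot <- integ(f, tas$mean_power)
  amp_band <- tas$mean_amplitude[sel]
  A_abs <- if (any(is.finite(amp_band))) max(amp_band, na.rm = TRUE) else NA_real_
  A_tot <- if (any(is.finite(tas$mean_amplitude)))
    max(tas$mean_amplitude, na.rm = TRUE) else NA_real_
  n_i <- sum(sel)
  fp <- if (any(is.finite(amp_band)))
    f[sel][which.max(amp_band)] else NA_real_
  data.frame(band = bd$name,
             E_abs = E_abs,
             e_rel = E_abs / (E_tot * n_i),
             A_abs = A_abs,
             a_rel = A_abs / (A_tot * n_i),
             f_peak_hz = fp,
             n_freqs = n_i,
             reliable = all(tas$coverage[sel] >= min_coverage),
             voices_per_octave = tas$voices_per_octave)
}

#' Band metrics for a whole catalogue
#'
#' Applies [band_metrics()] to every band of a catalogue. Bands whose
#' frequencies spend most of the averaging span outside the cone of
#' influence are flagged `reliable = FALSE` (for a 20-minute record this
#' excludes the MO-2 and MO-3 metabolic bands).
#'
#' @param tas a [time_average()] spectrum.
#' @param catalog a [band_catalog()].
#' @param energy energy convention, see [band_metrics()].
#' @param min_coverage reliability threshold, see [band_metrics()].
#' @return data frame with one row per band, in catalogue order.
#' @export
metrics_table <- function(tas, catalog, energy = c("trapezoid", "sum"),
                          min_coverage = 0.5) {
  stopifnot(inherits(catalog, "band_catalog"))
  energy <- match.arg(energy)
  if (!length(catalog))
    return(data.frame(band = character(0), E_abs = numeric(0),
                      e_rel = numeric(0), A_abs = numeric(0),
                      a_rel = numeric(0), f_peak_hz = numeric(0),
                      n_freqs = integer(0), reliable = logical(0),
                      voices_per_octave = integer(0)))
  do.call(rbind, lapply(catalog, function(b)
    band_metrics(tas, b, energy, min_coverage = min_coverage)))
}

#' Wavelet phase coherence between two simultaneous signals
#'
#' For each frequency of two scalograms computed on identical frequency and
#' time grids, forms the instantaneous phase difference
#' `dphi(t) = arg W_a(f, t) - arg W_b(f, t)` over admissible times (inside
#' both cones of influence and, optionally, a named analysis window) and
#' returns the resultant length
#' `Cphi(f) = sqrt(<cos dphi>^2 + <sin dphi>^2)`, a number in `[0, 1]`:
#' 0 means no phase relation, 1 a fixed phase relation.
#'
#' @param scal_a,scal_b `scalogram`s on identical grids.
#' @param window `NULL`, a window name present on both scalograms, or a
#'   `c(start_s, end_s)` interval.
#' @return object of class `wpco_spectrum`: `freqs_hz`, `cphi` (`NA` at
#'   frequencies with no admissible times), `n_times`, the pair label and
#'   window label.
#' @export
wpco <- function(scal_a, scal_b, window = NULL) {
  stopifnot(inherits(scal_a, "scalogram"), inherits(scal_b, "scalogram"))
  if (length(scal_a$freqs_hz) != length(scal_b$freqs_hz) ||
      any(abs(scal_a$freqs_hz - scal_b$freqs_hz) >
            1e-9 * scal_a$freqs_hz))
    stop("scalograms must share the same frequency grid")
  if (length(scal_a$times_s) != length(scal_b$times_s) ||
      any(abs(scal_a$times_s - scal_b$times_s) > 1e-9))
    stop("scalograms must share the same time grid")
  tt <- scal_a$times_s
  if (is.null(window)) {
    sel_t <- rep(TRUE, length(tt)); wlab <- "all"
  } else {
    if (is.character(window)) {
      wlab <- window
      wa <- scal_a$windows[[window]]
      if (is.null(wa)) stop(sprintf("no window named '%s'", window))
      window <- wa
    } else wlab <- sprintf("[%g,%g)", window[1], window[2])
    sel_t <- tt >= window[1] & tt < window[2]
  }
  adm <- scal_a$coi & scal_b$coi &
    matrix(sel_t, nrow = nrow(scal_a$coi), ncol = length(tt), byrow = TRUE)
  dphi <- Arg(scal_a$coeffs) - Arg(scal_b$coeffs)
  n_adm <- rowSums(adm)
  cph <- ifelse(n_adm > 0,
                sqrt(rowSums(cos(dphi) * adm)^2 +
                       rowSums(sin(dphi) * adm)^2) / pmax(n_adm, 1L),
                NA_real_)
  structure(list(freqs_hz = scal_a$freqs_hz, cphi = cph, n_times = n_adm,
                 pair = paste(scal_a$label, scal_b$label, sep = " / "),
                 window = wlab),
            class = "wpco_spectrum")
}

#' @export
print.wpco_spectrum <- function(x, ...) {
  cat(sprintf("<wpco_spectrum> %s, window %s: %d frequencies (%d with no admissible times)\n",
              x$pair, x$window, length(x$freqs_hz), sum(is.na(x$cphi))))
  invisible(x)
}

#' @export
plot.wpco_spectrum <- function(x, ...) {
  graphics::plot(x$freqs_hz, x$cphi, type = "l", log = "x", ylim = c(0, 1),
                 xlab = "frequency (Hz)", ylab = expression(C[phi]), ...)
  invisible(x)
}

#' Band-average phase coherence
#'
#' Arithmetic mean of the per-frequency phase coherence over the grid
#' frequencies of one band (only frequencies with admissible time points
#' contribute).
#'
#' @param w a [wpco()] spectrum.
#' @param bd an [band()].
#' @return list with `band`, `cphi_band`, `n_freqs` (contributing
#'   frequencies).
#' @export
band_coherence <- function(w, bd) {
  stopifnot(inherits(w, "wpco_spectrum"), inherits(bd, "osc_band"))
  sel <- w$freqs_hz >= bd$f_lo_hz & w$freqs_hz < bd$f_hi_hz
  if (!any(sel)) stop(sprintf("band '%s' contains no grid frequencies", bd$name))
  v <- w$cphi[sel]
  if (all(is.na(v)))
    stop(sprintf("band '%s' has no frequencies with admissible times", bd$name))
  list(band = bd$name, cphi_band = mean(v, na.rm = TRUE),
       n_freqs = sum(!is.na(v)))
}

#' @export
as.data.frame.wpco_spectrum <- function(x, ...) {
  data.frame(freq_hz = x$freqs_hz, cphi = x$cphi, n_times = x$n_times,
             pair = x$pair, window = x$window)
}
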