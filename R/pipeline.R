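#' Analysis configuration
#'
#' All tunable parameters of the per-subject chain, with defaults matching
#' the reference protocol: a 600 s baseline followed by a 600 s stimulus
#' window, LDF analysed from 1.5e-3 Hz up to `min(fs/4, 6)` Hz,
#' reconstructed metabolic biomarkers analysed from 1.5e-3 to 0.05 Hz at
#' 1 Hz reconstruction rate, 16 voices per octave, cone-of-influence
#' restricted averages, trapezoidal band energies and not-a-knot spline
#' reconstruction. Phase coherence between the metabolic MO-1 and vascular
#' EDHF oscillators is evaluated on the shared low-frequency grid after
#' anti-aliased decimation of the LDF record to the metabolic rate.
#'
#' @param baseline_s,stimulus_s analysis window durations (s).
#' @param recon_fs_hz reconstruction rate for metabolic biomarkers (Hz).
#' @param voices_per_octave wavelet grid density.
#' @param f_min_hz lower edge of every analysed grid (Hz).
#' @param f_max_metabolic_hz upper edge of the metabolic grid (Hz).
#' @param f_max_ldf_hz upper edge of the LDF grid, `NULL` for
#'   `min(fs/4, 6)`.
#' @param coi_only restrict time averages to the cone of influence.
#' @param energy band-energy convention, `"trapezoid"` or `"sum"`.
#' @param boundary spline boundary condition.
#' @param window_nm fluorophore search half-width (nm).
#' @param decimate_ldf decimate the LDF record (to `recon_fs_hz`) before
#'   the coherence branch; also used for the LDF band analysis when
#'   `ldf_fast = TRUE`.
#' @param ldf_fast analyse LDF bands on the decimated record (drops the
#'   cardiac and respiratory bands; several times faster).
#' @param seed seed stamped into outputs (provenance only; the analysis
#'   itself is deterministic).
#' @return object of class `analysis_config`.
#' @export
analysis_config <- function(baseline_s = 600, stimulus_s = 600,
                            recon_fs_hz = 1, voices_per_octave = 16L,
                            f_min_hz = 1.5e-3, f_max_metabolic_hz = 0.05,
                            f_max_ldf_hz = NULL, coi_only = TRUE,
                            energy = c("trapezoid", "sum"),
                            boundary = c("not-a-knot", "natural"),
                            window_nm = 10, decimate_ldf = TRUE,
                            ldf_fast = FALSE, seed = NA_integer_) {
  structure(list(baseline_s = baseline_s, stimulus_s = stimulus_s,
                 recon_fs_hz = recon_fs_hz,
                 voices_per_octave = as.integer(voices_per_octave),
                 f_min_hz = f_min_hz,
                 f_max_metabolic_hz = f_max_metabolic_hz,
                 f_max_ldf_hz = f_max_ldf_hz, coi_only = coi_only,
                 energy = match.arg(energy), boundary = match.arg(boundary),
                 window_nm = window_nm, decimate_ldf = decimate_ldf,
                 ldf_fast = ldf_fast, seed = seed),
            class = "analysis_config")
}

default_windows <- function(config) {
  list(baseline = c(0, config$baseline_s),
       pe = c(config$baseline_s, config$baseline_s + config$stimulus_s))
}

# truncate a uniform series to [t0, t_max] (used to align grids for WPCO)
crop_series <- function(series, t_max) {
  tt <- series_times(series)
  keep <- tt <= t_max + 1e-9
  out <- uniform_series(series$values[keep], fs_hz = series$fs_hz,
                        t0_seconds = series$t0_seconds, label = series$label)
  out$windows <- lapply(series$windows, function(w)
    c(w[1], min(w[2], t_max + 1 / series$fs_hz)))
  out
}

#' Analyse one subject end-to-end
#'
#' Runs the full per-subject chain on a simultaneous LDF + spectral
#' recording: biomarker extraction from the spectra, spline reconstruction,
#' Morlet wavelet transforms of the LDF record and of both reconstructed
#' biomarkers, per-window time-averaged spectra and band metrics, wavelet
#' phase coherence between each metabolic signal and the LDF record on a
#' shared low-frequency grid, and per-window perfusion (and, when
#' reflectance observations are supplied, oxygen saturation).
#'
#' @param ldf a [uniform_series()] LDF record (windows optional; the
#'   config's windows are attached if absent).
#' @param spectra list of [emission_spectrum()]s.
#' @param so2_obs optional named list (one entry per window) with
#'   `wavelengths_nm` and `mu_a` for [estimate_so2()].
#' @param config an [analysis_config()].
#' @param extinction an [extinction_table()] for the saturation estimates.
#' @return object of class `subject_analysis` with elements
#'   `biomarkers` (per-spectrum data frame), `ldf_metrics`, `met_metrics`
#'   (band-metric data frames, one row per band and window),
#'   `coherence` (per window and metabolic signal, MO-1/EDHF band values),
#'   `summary_vars` (per-window scalar variables) and the `config`.
#' @export
analyze_subject <- function(ldf, spectra, so2_obs = NULL,
                            config = analysis_config(),
                            extinction = extinction_table()) {
  stopifnot(inherits(ldf, "uniform_series"))
  windows <- if (length(ldf$windows)) ldf$windows else default_windows(config)
  ldf <- segment(ldf, windows)

  ## -- spectra -> biomarkers -> reconstruction ------------------------
  bio <- metabolic_series(spectra, window_nm = config$window_nm)
  knots_t <- bio$t_minutes * 60
  recon <- lapply(c(nadph_normalised = "nadph_normalised",
                    rr_index = "rr_index"), function(v) {
    ser <- irregular_series(knots_t, bio[[v]], label = v)
    spline_reconstruct(ser, fs_hz = config$recon_fs_hz,
                       boundary = config$boundary)
  })
  t_met_max <- max(knots_t)
  met_windows <- lapply(windows, function(w)
    c(w[1], min(w[2], t_met_max + 1 / config$recon_fs_hz)))
  recon <- lapply(recon, segment, windows = met_windows)

  ## -- wavelet transforms ---------------------------------------------
  met_par <- wavelet_params(config$f_min_hz, config$f_max_metabolic_hz,
                            config$voices_per_octave)
  ldf_for_bands <- ldf
  if (config$ldf_fast && config$decimate_ldf &&
      ldf$fs_hz > config$recon_fs_hz)
    ldf_for_bands <- decimate_series(ldf, round(ldf$fs_hz / config$recon_fs_hz))
  f_max_ldf <- if (is.null(config$f_max_ldf_hz))
    min(ldf_for_bands$fs_hz / 4, 6) else config$f_max_ldf_hz
  ldf_par <- wavelet_params(config$f_min_hz, f_max_ldf,
                            config$voices_per_octave)
  scal_ldf <- morlet_cwt(ldf_for_bands, ldf_par)
  scal_met <- lapply(recon, morlet_cwt, params = met_par)

  ## -- band metrics per window ----------------------------------------
  ldf_cat <- band_catalog("mouse_ldf")
  if (config$ldf_fast)  # decimated record has no cardiac/respiratory content
    ldf_cat <- structure(ldf_cat[vapply(ldf_cat, function(b)
      b$f_hi_hz <= f_max_ldf, TRUE)],
      id = "mouse_ldf", class = "band_catalog")
  met_cat <- band_catalog("metabolic")
  per_window <- function(scal, cat) {
    do.call(rbind, lapply(names(windows), function(w) {
      tas <- time_average(scal, w, coi_only = config$coi_only)
      cbind(window = w, metrics_table(tas, cat, energy = config$energy))
    }))
  }
  ldf_metrics <- per_window(scal_ldf, ldf_cat)
  met_metrics <- do.call(rbind, lapply(names(scal_met), function(sig)
    cbind(signal = sig, per_window(scal_met[[sig]], met_cat))))

  ## -- phase coherence on the shared low-frequency grid ----------------
  ldf_lf <- ldf
  if (config$decimate_ldf && ldf$fs_hz > config$recon_fs_hz)
    ldf_lf <- decimate_series(ldf, round(ldf$fs_hz / config$recon_fs_hz))
  ldf_lf <- crop_series(ldf_lf, t_met_max)
  ldf_lf$windows <- met_windows
  scal_ldf_lf <- morlet_cwt(ldf_lf, met_par)
  mo1 <- met_cat[[1]]
  coh <- do.call(rbind, lapply(names(scal_met), function(sig) {
    do.call(rbind, lapply(names(met_windows), function(w) {
      wsp <- wpco(scal_met[[sig]], scal_ldf_lf, window = w)
      bc <- band_coherence(wsp, mo1)
      data.frame(signal = sig, window = w, band = bc$band,
                 cphi = bc$cphi_band, n_freqs = bc$n_freqs)
    }))
  }))

  ## -- per-window scalar summary variables -----------------------------
  tt <- series_times(ldf)
  sv <- do.call(rbind, lapply(names(windows), function(w) {
    win <- windows[[w]]
    in_w <- tt >= win[1] & tt < win[2]
    in_b <- bio$t_minutes * 60 >= win[1] & bio$t_minutes * 60 < win[2]
    so2 <- NA_real_
    if (!is.null(so2_obs[[w]])) {
      est <- estimate_so2(so2_obs[[w]]$wavelengths_nm, so2_obs[[w]]$mu_a,
                          extinction)
      so2 <- est$so2_percent
    }
    data.frame(window = w,
               perfusion = mean(ldf$values[in_w]),
               so2 = so2,
               nadph_normalised = mean(bio$nadph_normalised[in_b]),
               rr_index = mean(bio$rr_index[in_b]))
  }))

  structure(list(biomarkers = bio, ldf_metrics = ldf_metrics,
                 met_metrics = met_metrics, coherence = coh,
                 summary_vars = sv, windows = windows, config = config),
            class = "subject_analysis")
}

#' @export
print.subject_analysis <- function(x, ...) {
  cat("<subject_analysis>\n")
  cat(sprintf("  %d spectra, windows: %s\n", nrow(x$biomarkers),
              paste(names(x$windows), collapse = ", ")))
  cat(sprintf("  LDF bands: %s\n",
              paste(unique(x$ldf_metrics$band), collapse = ", ")))
  cat("  MO-1/EDHF phase coherence:\n")
  print(x$coherence, row.names = FALSE)
  invisible(x)
}

#' Flatten a subject analysis into wide metric rows
#'
#' One row per analysis window, with scalar variables (perfusion, SO2,
#' mean biomarkers), per-band relative energy / amplitude / peak frequency
#' (columns like `EDHF_e`, `EDHF_a`, `EDHF_f`, `nadph_MO1_e`, ...) and the
#' MO-1/EDHF coherences (`coh_nadph_mo1_edhf`, `coh_rr_mo1_edhf`).
#' Unreliable bands keep their values; reliability travels in the
#' per-analysis tables.
#'
#' @param analysis a [analyze_subject()] result.
#' @param subject,group identifier columns to prepend.
#' @return data frame, one row per window.
#' @export
subject_metrics <- function(analysis, subject = "s1", group = "g1") {
  stopifnot(inherits(analysis, "subject_analysis"))
  rows <- lapply(unique(analysis$summary_vars$window), function(w) {
    row <- data.frame(subject = subject, group = group, window = w)
    row <- cbind(row, analysis$summary_vars[
      analysis$summary_vars$window == w,
      c("perfusion", "so2", "nadph_normalised", "rr_index")])
    lm <- analysis$ldf_metrics[analysis$ldf_metrics$window == w, ]
    for (i in seq_len(nrow(lm))) {
      row[[paste0(lm$band[i], "_e")]] <- lm$e_rel[i]
      row[[paste0(lm$band[i], "_a")]] <- lm$a_rel[i]
      row[[paste0(lm$band[i], "_f")]] <- lm$f_peak_hz[i]
    }
    mm <- analysis$met_metrics[analysis$met_metrics$window == w &
                                 analysis$met_metrics$band == "MO1", ]
    for (i in seq_len(nrow(mm))) {
      sig <- if (mm$signal[i] == "nadph_normalised") "nadph" else "rr"
      row[[paste0(sig, "_MO1_e")]] <- mm$e_rel[i]
      row[[paste0(sig, "_MO1_a")]] <- mm$a_rel[i]
      row[[paste0(sig, "_MO1_f")]] <- mm$f_peak_hz[i]
    }
    ch <- analysis$coherence[analysis$coherence$window == w, ]
    for (i in seq_len(nrow(ch))) {
      sig <- if (ch$signal[i] == "nadph_normalised") "nadph" else "rr"
      row[[paste0("coh_", sig, "_mo1_edhf")]] <- ch$cphi[i]
    }
    row
  })
  do.call(rbind, rows)
}

#' Run a whole study
#'
#' Analyses every subject, averages duplicate recordings of the same
#' subject at the metrics level, and applies the statistical layer:
#' normality screen, within-group paired comparisons (baseline vs
#' stimulus), between-group unpaired comparisons per window, a set of
#' microvascular-metabolic correlations, and the mean-and-SD summary
#' table. A failing subject is skipped with a warning and the rest of the
#' study completes.
#'
#' @param subjects list of subject recordings; each element needs `ldf`,
#'   `spectra`, optional `so2_obs`, and `id` / `group` fields (the format
#'   produced by [generate_study()]).
#' @param config an [analysis_config()].
#' @param correlations list of `c(var_x, var_y)` pairs for the pooled
#'   per-group correlation analysis; `NULL` for a default set relating
#'   vascular band energies to metabolic MO-1 metrics.
#' @return object of class `study_analysis`: `metrics` (wide per
#'   subject-window table), `normality`, `comparisons`, `correlations`,
#'   `table1` (summary table with a `formatted` attribute), `failed`
#'   (ids of skipped subjects), `config`.
#' @export
run_study <- function(subjects, config = analysis_config(),
                      correlations = NULL) {
  metr <- list()
  failed <- character(0)
  for (sub in subjects) {
    res <- tryCatch(
      analyze_subject(sub$ldf, sub$spectra, so2_obs = sub$so2_obs,
                      config = config),
      error = function(e) {
        warning(sprintf("subject '%s' skipped: %s", sub$id,
                        conditionMessage(e)), call. = FALSE)
        NULL
      })
    if (is.null(res)) { failed <- c(failed, sub$id); next }
    metr[[length(metr) + 1L]] <- subject_metrics(res, subject = sub$id,
                                                 group = sub$group)
  }
  if (!length(metr)) stop("no subject could be analysed")
  metrics <- do.call(rbind, metr)
  # duplicate recordings of one subject: average at the metrics level
  key <- interaction(metrics$subject, metrics$window, drop = TRUE)
  if (anyDuplicated(key)) {
    num <- setdiff(names(metrics)[vapply(metrics, is.numeric, TRUE)],
                   c("subject", "group", "window"))
    agg <- stats::aggregate(metrics[num],
                            by = metrics[c("subject", "group", "window")],
                            FUN = mean)
    metrics <- agg
  }
  stats_out <- study_statistics(metrics, correlations = correlations)
  structure(c(list(metrics = metrics, failed = failed, config = config),
              stats_out),
            class = "study_analysis")
}

#' Statistical layer over a subject-metrics table
#'
#' Applies the normality screen, within-group paired and between-group
#' unpaired comparisons for every variable, the pooled per-group
#' correlation set, and the mean-and-SD summary table. Usable directly on
#' a metrics CSV read back with [read_metrics_csv()].
#'
#' @param metrics wide subject-metrics data frame (columns `subject`,
#'   `group`, `window`, variables).
#' @param correlations list of `c(var_x, var_y)` pairs; `NULL` for the
#'   default vascular-metabolic set.
#' @return list with `normality`, `comparisons`, `correlations`, `table1`
#'   (each `NULL` when fewer than 2 subjects per group are available).
#' @export
study_statistics <- function(metrics, correlations = NULL) {
  groups <- unique(metrics$group)
  variables <- setdiff(names(metrics)[vapply(metrics, is.numeric, TRUE)],
                       c("subject", "group", "window"))
  enough <- all(table(metrics$group[metrics$window == metrics$window[1]]) >= 2)
  stats_out <- list(normality = NULL, comparisons = NULL,
                    correlations = NULL, table1 = NULL)
  if (length(groups) < 1 || !enough) {
    warning("fewer than 2 subjects in a group: statistics skipped")
    return(stats_out)
  }
  stats_out$normality <- suppressWarnings(normality_gate(metrics, variables))
  cmp <- list()
  for (v in variables) {
    for (g in groups)
      cmp[[length(cmp) + 1L]] <- tryCatch(
        compare_metrics(metrics, v, "within", group = g),
        error = function(e) NULL)
    if (length(groups) >= 2)
      for (w in unique(metrics$window))
        cmp[[length(cmp) + 1L]] <- tryCatch(
          compare_metrics(metrics, v, "between", window = w,
                          groups = groups[1:2]),
          error = function(e) NULL)
  }
  stats_out$comparisons <- do.call(rbind, cmp)
  if (is.null(correlations))
    correlations <- list(c("EDHF_e", "nadph_MO1_e"),
                         c("EDHF_e", "rr_MO1_a"),
                         c("endothelial_NO_e", "nadph_MO1_e"),
                         c("neurogenic_e", "nadph_MO1_e"),
                         c("myogenic_e", "nadph_MO1_e"),
                         c("perfusion", "rr_MO1_a"),
                         c("endothelial_NO_f", "nadph_MO1_e"),
                         c("endothelial_NO_f", "so2"))
  cors <- list()
  for (g in groups) for (pr in correlations)
    if (all(pr %in% names(metrics)))
      cors[[length(cors) + 1L]] <- tryCatch(
        correlate_metrics(metrics, pr[1], pr[2], group = g,
                          subset = "pooled"),
        error = function(e) NULL)
  stats_out$correlations <- do.call(rbind, cors)
  stats_out$table1 <- suppressWarnings(summary_table(metrics, variables))
  stats_out
}

#' @export
print.study_analysis <- function(x, ...) {
  cat(sprintf("<study_analysis> %d subjects (%s)%s\n",
              length(unique(x$metrics$subject)),
              paste(sprintf("%s: %d", names(table(x$metrics$group) / 2),
                            table(x$metrics$group) / 2), collapse = ", "),
              if (length(x$failed))
                sprintf(", %d failed", length(x$failed)) else ""))
  if (!is.null(x$comparisons)) {
    sig <- x$comparisons[x$comparisons$significant, ]
    cat(sprintf("  %d comparisons computed, %d significant at p < 0.05\n",
                nrow(x$comparisons), nrow(sig)))
  }
  if (!is.null(x$correlations))
    cat(sprintf("  %d correlations computed, %d relevant (p <= 0.05, |r| > 0.5)\n",
                nrow(x$correlations), sum(x$correlations$relevant)))
  invisible(x)
}

#' @export
summary.study_analysis <- function(object, ...) {
  cat("Summary table (mean ± SD per group and window):\n")
  print(attr(object$table1, "formatted"), row.names = FALSE)
  invisible(object)
}
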