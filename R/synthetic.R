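#' Band-limited oscillator specification
#'
#' One simulated physiological oscillator: a phase-diffused sinusoid whose
#' instantaneous phase performs a Wiener walk around uniform rotation,
#' which keeps its energy inside a frequency band (as real vasomotion
#' components do) instead of at a spectral line. The default jitter gives
#' roughly a +/-20 percent instantaneous-frequency spread when averaged
#' over one oscillation period (`sd = 0.4 * pi * sqrt(f)` rad per sqrt
#' second). During the stimulus window the amplitude is multiplied by
#' `pe_factor`, ramped smoothly over 10 s to avoid an artificial broadband
#' edge.
#'
#' @param name oscillator name (conventionally a band name).
#' @param freq_hz nominal frequency (Hz).
#' @param amplitude amplitude (a.u.), >= 0.
#' @param phase_jitter_sd phase-diffusion standard deviation (rad/sqrt(s));
#'   0 gives a pure sinusoid. Default: 20 percent relative spread.
#' @param pe_factor multiplicative amplitude change during the stimulus
#'   window (1 = no reactivity).
#' @return object of class `oscillator_spec`.
#' @export
oscillator_spec <- function(name, freq_hz, amplitude,
                            phase_jitter_sd = 0.4 * pi * sqrt(freq_hz),
                            pe_factor = 1) {
  stopifnot(freq_hz > 0, amplitude >= 0, phase_jitter_sd >= 0, pe_factor >= 0)
  structure(list(name = name, freq_hz = freq_hz, amplitude = amplitude,
                 phase_jitter_sd = phase_jitter_sd, pe_factor = pe_factor),
            class = "oscillator_spec")
}

#' Default mouse LDF oscillator set
#'
#' Six oscillators placed inside the six mouse vasomotion bands (cardiac,
#' respiratory, myogenic, neurogenic, endothelial NO-dependent, EDHF), with
#' amplitudes in perfusion units chosen so that the slow endothelial
#' components have a band signal-to-noise ratio near 2 under the default
#' 1/f noise level.
#'
#' @param edhf_pe_factor amplitude factor applied to the EDHF oscillator
#'   during the stimulus window (emulates endothelial reactivity to the
#'   vasoconstrictor; < 1 suppresses, > 1 enhances).
#' @return list of [oscillator_spec()]s.
#' @export
ldf_oscillators <- function(edhf_pe_factor = 1) {
  list(
    oscillator_spec("cardiac",        3.0,   6),
    oscillator_spec("respiratory",    0.7,   4),
    oscillator_spec("myogenic",       0.10,  3),
    oscillator_spec("neurogenic",     0.030, 2.5),
    oscillator_spec("endothelial_NO", 0.014, 2),
    oscillator_spec("EDHF",           0.007, 2, pe_factor = edhf_pe_factor))
}

#' Synthetic study configuration
#'
#' Defaults emulate the target experiment: two groups of 5 ("WT") and 6
#' ("KO") animals, a 600 s baseline followed by a 600 s phenylephrine
#' stimulus, LDF sampled at 20 Hz, one emission spectrum per minute,
#' 1/f noise, and opposite EDHF reactivity in the two groups (amplitude
#' suppressed under the stimulus in group WT, enhanced in group KO). Group
#' perfusion levels and oxygen-saturation values follow the magnitudes
#' typical for mouse skin (baseline perfusion near 174 and 198 perfusion
#' units, saturation near 45-48 percent).
#'
#' @param n_per_group named integer vector of group sizes.
#' @param n_replicates recordings per subject (default 2, mirroring the
#'   protocol of repeating each experiment in duplicate and averaging the
#'   per-variable results).
#' @param baseline_s,stimulus_s window durations (s).
#' @param fs_ldf_hz LDF sampling rate (Hz).
#' @param spectra_per_minute emission-spectrum acquisition rate (1/min).
#' @param coupling_rho phase-coupling strength in `[0, 1]` between the
#'   metabolic MO-1 oscillator and the vascular EDHF oscillator.
#' @param noise_beta spectral exponent of the LDF `1/f^beta` noise.
#' @param noise_sd total standard deviation of the LDF noise (perfusion
#'   units); the default gives EDHF-band SNR near 2.
#' @param spectrum_noise_sd per-wavelength intensity noise on spectra (a.u.).
#' @param mo1_freq_hz metabolic oscillator frequency (Hz, inside MO-1).
#' @param mod_depth relative modulation depth of the NAD(P)H and FAD+
#'   amplitudes at the MO-1 frequency.
#' @param groups named list of per-group settings; each entry is a list
#'   with `dc` (baseline perfusion), `dc_pe_factor`, `edhf_pe_factor`,
#'   `so2` (named vector, true saturation percent per window) and
#'   optionally `base_amps` (baseline fluorophore amplitudes; the defaults
#'   give the two groups different metabolic baselines: redox ratio 2.2
#'   vs 2.0, normalised NAD(P)H 1.7 vs 1.9).
#' @param seed base random seed; every subject derives its own stream from
#'   it, so regeneration is fully deterministic.
#' @return object of class `synth_config`.
#' @export
synth_config <- function(n_per_group = c(WT = 5L, KO = 6L),
                         n_replicates = 2L,
                         baseline_s = 600, stimulus_s = 600,
                         fs_ldf_hz = 20, spectra_per_minute = 1,
                         coupling_rho = 0.8,
                         noise_beta = 1, noise_sd = 2.8,
                         spectrum_noise_sd = 0.02,
                         mo1_freq_hz = 0.007, mod_depth = 0.15,
                         groups = NULL, seed = 1L) {
  stopifnot(baseline_s > 0, stimulus_s > 0, fs_ldf_hz > 0,
            coupling_rho >= 0, coupling_rho <= 1, noise_sd >= 0)
  if (is.null(groups)) {
    groups <- list(
      # per-group metabolic baselines: normalised NAD(P)H 1.7 vs 1.9,
      # redox ratio 2.2 vs 2.0 (the knockout-like group is shifted
      # towards the oxidised state)
      WT = list(dc = 174.0, dc_pe_factor = 162.8 / 174.0,
                edhf_pe_factor = 0.5,
                so2 = c(baseline = 47.3, pe = 44.9),
                base_amps = c(elastin = 2.0, nadph = 3.4, fad = 3.4 / 2.2)),
      KO = list(dc = 197.6, dc_pe_factor = 184.0 / 197.6,
                edhf_pe_factor = 2.0,
                so2 = c(baseline = 48.3, pe = 45.5),
                base_amps = c(elastin = 2.0, nadph = 3.8, fad = 3.8 / 2.0)))
    groups <- groups[names(n_per_group)]
  }
  if (!all(names(n_per_group) %in% names(groups)))
    stop("every group needs an entry in `groups`")
  structure(list(n_per_group = n_per_group,
                 n_replicates = as.integer(n_replicates),
                 baseline_s = baseline_s, stimulus_s = stimulus_s,
                 fs_ldf_hz = fs_ldf_hz, spectra_per_minute = spectra_per_minute,
                 coupling_rho = coupling_rho, noise_beta = noise_beta,
                 noise_sd = noise_sd, spectrum_noise_sd = spectrum_noise_sd,
                 mo1_freq_hz = mo1_freq_hz, mod_depth = mod_depth,
                 groups = groups, seed = as.integer(seed)),
            class = "synth_config")
}

# derive a child seed deterministically, kept inside 32-bit integer range
child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483647)
}

# smooth 10 s half-cosine ramp from 0 (before t_on) to 1 (after t_on + ramp_s)
pe_ramp <- function(t, t_on, ramp_s = 10) {
  w <- (t - t_on) / ramp_s
  ifelse(w <= 0, 0, ifelse(w >= 1, 1, 0.5 * (1 - cos(pi * w))))
}

# Wiener-diffused phase track: 2*pi*f*t plus a random walk
phase_track <- function(n, fs, freq_hz, jitter_sd, phi0 = 0) {
  t <- (seq_len(n) - 1L) / fs
  walk <- if (jitter_sd > 0)
    cumsum(stats::rnorm(n, 0, jitter_sd / sqrt(fs))) else 0
  phi0 + 2 * pi * freq_hz * t + walk
}

# 1/f^beta Gaussian noise with a given total standard deviation
pink_noise <- function(n, beta, sd_total) {
  if (sd_total <= 0) return(rep(0, n))
  n2 <- 2^ceiling(log2(max(n, 2)))
  w <- stats::rnorm(n2)
  W <- stats::fft(w)
  j <- 0:(n2 - 1)
  fbin <- pmin(j, n2 - j) / n2        # cyclic frequency per bin, 0..0.5
  shape <- c(0, fbin[-1]^(-beta / 2)) # kill DC
  x <- Re(stats::fft(W * shape, inverse = TRUE))[1:n] / n2
  x <- x - mean(x)
  x * sd_total / stats::sd(x)
}

#' Generate a synthetic LDF perfusion record
#'
#' Sum of a perfusion DC level, six band-resident phase-diffused
#' oscillators and `1/f^beta` noise, with amplitudes (and the DC level)
#' switching by their stimulus factors at the baseline/stimulus boundary
#' through a smooth 10 s ramp. Fully deterministic given the seed.
#'
#' @param config a [synth_config()].
#' @param seed integer seed for this record.
#' @param oscillators list of [oscillator_spec()]s; default
#'   [ldf_oscillators()].
#' @param dc baseline perfusion level (perfusion units).
#' @param dc_pe_factor multiplicative DC change during the stimulus.
#' @return list with `series` (a [uniform_series()] with `baseline` and
#'   `pe` windows) and `truth` (oscillator specs, noise parameters, seed,
#'   and the realised EDHF phase track downsampled to 1 Hz, used to couple
#'   the metabolic generator).
#' @export
generate_ldf <- function(config, seed = config$seed,
                         oscillators = ldf_oscillators(),
                         dc = 174, dc_pe_factor = 1) {
  stopifnot(inherits(config, "synth_config"))
  fs <- config$fs_ldf_hz
  dur <- config$baseline_s + config$stimulus_s
  n <- round(dur * fs)
  t <- (seq_len(n) - 1L) / fs
  ramp <- pe_ramp(t, config$baseline_s)
  set.seed(seed)
  sig <- dc * (1 + (dc_pe_factor - 1) * ramp)
  edhf_phase <- NULL
  for (os in oscillators) {
    phi <- phase_track(n, fs, os$freq_hz, os$phase_jitter_sd,
                       phi0 = stats::runif(1, 0, 2 * pi))
    env <- os$amplitude * (1 + (os$pe_factor - 1) * ramp)
    sig <- sig + env * cos(phi)
    if (os$name == "EDHF") edhf_phase <- phi
  }
  sig <- sig + pink_noise(n, config$noise_beta, config$noise_sd)
  ser <- uniform_series(sig, fs_hz = fs, label = "LDF",
                        windows = list(baseline = c(0, config$baseline_s),
                                       pe = c(config$baseline_s, dur)))
  step <- max(1L, round(fs))  # 1 Hz track for coupling the metabolic phase
  truth <- list(oscillators = oscillators, dc = dc,
                dc_pe_factor = dc_pe_factor,
                noise_beta = config$noise_beta, noise_sd = config$noise_sd,
                seed = seed,
                edhf_phase_1hz = if (is.null(edhf_phase)) NULL
                                 else edhf_phase[seq(1L, n, by = step)])
  list(series = ser, truth = truth)
}

# Gaussian crosstalk matrix between fluorophore emission peaks
gauss_crosstalk <- function(centres = FLUOROPHORE_CENTRES, sigma_nm = 15) {
  outer(centres, centres, function(a, b) exp(-(a - b)^2 / (2 * sigma_nm^2)))
}

#' Generate a synthetic emission-spectrum time series
#'
#' Builds one spectrum per sampling time (default: one per minute for 20
#' minutes) as the sum of three Gaussian fluorophore peaks (elastin 450 nm,
#' NAD(P)H 490 nm, FAD+ 550 nm; sigma 15 nm) on a 400-650 nm grid at 1 nm,
#' plus optional white intensity noise. The NAD(P)H and FAD+ amplitudes are
#' modulated in anti-phase at the MO-1 frequency (redox turnover), so the
#' redox ratio and normalised NAD(P)H oscillate in the MO-1 band.
#'
#' "Amplitude" here means the window-maximum amplitude of the noiseless
#' composite spectrum, i.e. the quantity the downstream peak extraction
#' measures: requested amplitudes are converted to Gaussian heights
#' through the 3x3 peak-overlap (crosstalk) matrix and refined by a few
#' fixed-point steps, so on noise-free spectra the extraction recovers the
#' requested amplitudes (and their ratios) essentially exactly.
#'
#' When `coupled_phase` is supplied (the LDF EDHF phase track at 1 Hz) and
#' `config$coupling_rho > 0`, the metabolic phase is the argument of the
#' phasor mixture `rho * exp(i phase_EDHF) + (1 - rho) * exp(i phase_indep)`;
#' `rho = 1` copies the vascular phase exactly and `rho = 0` leaves the two
#' oscillators independent.
#'
#' @param config a [synth_config()].
#' @param seed integer seed for this spectral record.
#' @param coupled_phase optional numeric vector: shared phase track at 1 Hz.
#' @param base_amps named vector of baseline composite amplitudes at the
#'   three peak centres (a.u.); the defaults give a normalised NAD(P)H near
#'   1.7 and a redox ratio near 2.2.
#' @return list with `spectra` (list of [emission_spectrum()]) and `truth`
#'   (per-timepoint target amplitudes and ratios, the metabolic phase at
#'   the sample times, modulation depth, coupling, seed).
#' @export
generate_spectra <- function(config, seed = config$seed, coupled_phase = NULL,
                             base_amps = c(elastin = 2.0, nadph = 3.4,
                                           fad = 3.4 / 2.2)) {
  stopifnot(inherits(config, "synth_config"))
  dur <- config$baseline_s + config$stimulus_s
  n_spec <- floor(dur / 60 * config$spectra_per_minute)
  t_s <- (seq_len(n_spec) - 1L) * 60 / config$spectra_per_minute
  set.seed(seed)
  n_1hz <- round(dur)
  phi_ind <- phase_track(n_1hz, 1, config$mo1_freq_hz,
                         0.4 * pi * sqrt(config$mo1_freq_hz),
                         phi0 = stats::runif(1, 0, 2 * pi))
  rho <- config$coupling_rho
  phi_met <- if (!is.null(coupled_phase) && rho > 0) {
    m <- min(length(coupled_phase), n_1hz)
    Arg(rho * exp(1i * coupled_phase[1:m]) +
          (1 - rho) * exp(1i * phi_ind[1:m]))
  } else phi_ind
  phi_at <- phi_met[pmin(round(t_s) + 1L, length(phi_met))]
  depth <- config$mod_depth
  wl <- 400:650
  Minv <- solve(gauss_crosstalk())
  gauss <- outer(wl, FLUOROPHORE_CENTRES, function(w, c) exp(-(w - c)^2 / 450))
  spectra <- vector("list", n_spec)
  amp_tab <- matrix(NA_real_, n_spec, 3,
                    dimnames = list(NULL, names(FLUOROPHORE_CENTRES)))
  win_sel <- lapply(FLUOROPHORE_CENTRES, function(ctr)
    which(wl >= ctr - 10 & wl <= ctr + 10))
  for (m in seq_len(n_spec)) {
    a <- c(elastin = unname(base_amps["elastin"]),
           nadph = unname(base_amps["nadph"]) * (1 + depth * cos(phi_at[m])),
           fad = unname(base_amps["fad"]) * (1 - depth * cos(phi_at[m])))
    amp_tab[m, ] <- a
    h <- drop(Minv %*% a)
    # fixed-point refinement: make the window maxima of the composite
    # curve equal the requested amplitudes (peak overlap shifts the
    # maximum slightly off-centre, so one linear solve is not exact)
    for (it in 1:3) {
      cur <- drop(gauss %*% h)
      got <- vapply(win_sel, function(s) max(cur[s]), numeric(1))
      h <- h + drop(Minv %*% (a - got))
    }
    intens <- drop(gauss %*% h)
    if (config$spectrum_noise_sd > 0)
      intens <- intens + stats::rnorm(length(wl), 0, config$spectrum_noise_sd)
    spectra[[m]] <- emission_spectrum(wl, pmax(intens, 0),
                                      t_minutes = t_s[m] / 60)
  }
  list(spectra = spectra,
       truth = list(amplitudes = amp_tab,
                    rr_index = amp_tab[, "nadph"] / amp_tab[, "fad"],
                    nadph_normalised = amp_tab[, "nadph"] / amp_tab[, "elastin"],
                    phase = phi_at, mod_depth = depth,
                    coupling_rho = if (is.null(coupled_phase)) 0 else rho,
                    mo1_freq_hz = config$mo1_freq_hz, seed = seed))
}

#' Generate one synthetic subject
#'
#' One simultaneous LDF + spectral recording with phase coupling between
#' the vascular EDHF oscillator and the metabolic MO-1 oscillator, plus a
#' per-window reflectance observation carrying a known oxygen saturation.
#'
#' @param config a [synth_config()].
#' @param group name of the subject's group (must exist in
#'   `config$groups`).
#' @param subject_seed integer seed for this subject.
#' @return list with `ldf`, `spectra`, `so2_obs` (per-window absorption
#'   observations on the default extinction grid) and `truth`.
#' @export
generate_subject <- function(config, group, subject_seed) {
  stopifnot(inherits(config, "synth_config"))
  g <- config$groups[[group]]
  if (is.null(g)) stop(sprintf("unknown group '%s'", group))
  ldf <- generate_ldf(config, seed = child_seed(subject_seed, 1),
                      oscillators = ldf_oscillators(g$edhf_pe_factor),
                      dc = g$dc, dc_pe_factor = g$dc_pe_factor)
  spec_args <- list(config, seed = child_seed(subject_seed, 2),
                    coupled_phase = ldf$truth$edhf_phase_1hz)
  if (!is.null(g$base_amps)) spec_args$base_amps <- g$base_amps
  spec <- do.call(generate_spectra, spec_args)
  tab <- extinction_table()
  so2_obs <- lapply(g$so2, function(s) {
    c_oxy <- s / 100
    list(wavelengths_nm = tab$wavelengths_nm,
         mu_a = forward_absorption(c_oxy, 1 - c_oxy, tab))
  })
  list(ldf = ldf$series, spectra = spec$spectra, so2_obs = so2_obs,
       truth = list(group = group, subject_seed = subject_seed,
                    ldf = ldf$truth, spectra = spec$truth, so2 = g$so2))
}

#' Generate a whole synthetic study
#'
#' Produces `n_replicates` independent recordings per subject (same group
#' reactivity factors, different noise and phase realisations), mirroring
#' the duplicate-experiment protocol; [run_study()] averages replicate
#' metrics per subject before statistics.
#'
#' @param config a [synth_config()].
#' @return list of recordings (as from [generate_subject()]), each with
#'   `id` (shared by replicates of one subject) and `group` fields,
#'   deterministic in `config$seed`.
#' @export
generate_study <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  out <- list()
  idx <- 0L
  for (grp in names(config$n_per_group)) {
    ng <- config$n_per_group[[grp]]
    if (ng < 1L) next
    for (i in seq_len(ng)) {
      for (r in seq_len(max(config$n_replicates, 1L))) {
        idx <- idx + 1L
        sub <- generate_subject(config, grp,
                                child_seed(config$seed, 1000L + idx))
        sub$id <- sprintf("%s_%02d", grp, i)
        sub$group <- grp
        out[[sprintf("%s_r%d", sub$id, r)]] <- sub
      }
    }
  }
  out
}

#' Generate a noisy band-limited oscillator signal
#'
#' Convenience generator for coherence experiments: one phase-diffused
#' sinusoid plus white noise, with the noise level set by a band
#' signal-to-noise ratio defined as oscillator RMS over noise standard
#' deviation. An externally supplied phase track (or a phasor mixture of
#' it with an independent track) allows building signal pairs with a known
#' degree of phase coupling.
#'
#' @param duration_s record length (s).
#' @param fs_hz sampling rate (Hz).
#' @param freq_hz oscillator frequency (Hz).
#' @param amplitude oscillator amplitude.
#' @param snr oscillator RMS divided by noise SD (Inf for noiseless).
#' @param phase_jitter_sd phase diffusion (rad/sqrt(s)).
#' @param shared_phase optional phase track to couple to.
#' @param rho coupling strength to `shared_phase` in `[0, 1]`.
#' @param label signal label.
#' @return list with `series` (a [uniform_series()]) and `phase` (the
#'   realised phase track).
#' @export
generate_oscillator_series <- function(duration_s, fs_hz, freq_hz,
                                       amplitude = 1, snr = 1,
                                       phase_jitter_sd = 0.4 * pi * sqrt(freq_hz),
                                       shared_phase = NULL, rho = 0,
                                       label = "osc") {
  n <- round(duration_s * fs_hz)
  phi <- phase_track(n, fs_hz, freq_hz, phase_jitter_sd,
                     phi0 = stats::runif(1, 0, 2 * pi))
  if (!is.null(shared_phase) && rho > 0) {
    m <- min(length(shared_phase), n)
    phi[1:m] <- Arg(rho * exp(1i * shared_phase[1:m]) +
                      (1 - rho) * exp(1i * phi[1:m]))
  }
  v <- amplitude * cos(phi)
  if (is.finite(snr) && snr > 0)
    v <- v + stats::rnorm(n, 0, amplitude / sqrt(2) / snr)
  list(series = uniform_series(v, fs_hz = fs_hz, label = label), phase = phi)
}
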