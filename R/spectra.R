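#' Discrete autofluorescence emission spectrum
#'
#' Container for a single UV-excited skin autofluorescence emission spectrum,
#' as acquired once per minute by a fibre-optic fluorescence probe. The
#' wavelength grid must cover the three nominal fluorophore emission peaks
#' used downstream: elastin (450 nm), NAD(P)H (490 nm) and FAD+ (550 nm).
#'
#' @param wavelengths_nm strictly increasing emission wavelengths (nm).
#' @param intensities non-negative fluorescence intensities (arbitrary
#'   units), same length as `wavelengths_nm`.
#' @param t_minutes acquisition time since the start of the recording (min).
#' @return an object of class `emission_spectrum`.
#' @export
emission_spectrum <- function(wavelengths_nm, intensities, t_minutes = NA_real_) {
  wavelengths_nm <- as.numeric(wavelengths_nm)
  intensities <- as.numeric(intensities)
  if (length(wavelengths_nm) != length(intensities))
    stop("wavelengths and intensities must have the same length")
  if (length(wavelengths_nm) < 3L)
    stop("an emission spectrum needs at least 3 samples")
  if (any(diff(wavelengths_nm) <= 0))
    stop("wavelengths must be strictly increasing")
  if (any(!is.finite(intensities)) || any(intensities < 0))
    stop("intensities must be finite and non-negative")
  structure(
    list(wavelengths_nm = wavelengths_nm,
         intensities = intensities,
         t_minutes = as.numeric(t_minutes)[1L]),
    class = "emission_spectrum")
}

#' @export
print.emission_spectrum <- function(x, ...) {
  cat(sprintf("<emission_spectrum> %d points, %.0f-%.0f nm, t = %s min\n",
              length(x$wavelengths_nm), min(x$wavelengths_nm),
              max(x$wavelengths_nm),
              if (is.na(x$t_minutes)) "?" else format(x$t_minutes)))
  invisible(x)
}

# nominal emission-peak centres (nm) of the three skin fluorophores
FLUOROPHORE_CENTRES <- c(elastin = 450, nadph = 490, fad = 550)

#' Extract fluorophore peak amplitudes from an emission spectrum
#'
#' The amplitude of each fluorophore is the maximum raw intensity inside a
#' symmetric wavelength window centred on its nominal emission peak
#' (elastin 450 nm, NAD(P)H 490 nm, FAD+ 550 nm). No curve fitting or
#' baseline subtraction is applied.
#'
#' @param spectrum an [emission_spectrum()].
#' @param window_nm half-width of the search window around each nominal
#'   centre (nm); default 10.
#' @param centres named numeric vector of nominal peak centres (nm).
#' @return object of class `fluorophore_amplitudes`: a list with one entry
#'   per fluorophore, each holding `amplitude` (a.u.) and `wavelength_nm`
#'   (location of the window maximum).
#' @export
peak_amplitudes <- function(spectrum, window_nm = 10,
                            centres = FLUOROPHORE_CENTRES) {
  stopifnot(inherits(spectrum, "emission_spectrum"))
  if (!is.numeric(window_nm) || window_nm <= 0)
    stop("window_nm must be a positive half-width in nm")
  out <- lapply(seq_along(centres), function(i) {
    ctr <- centres[[i]]
    sel <- spectrum$wavelengths_nm >= ctr - window_nm &
      spectrum$wavelengths_nm <= ctr + window_nm
    if (!any(sel))
      stop(sprintf("spectrum grid does not cover the %s channel (%g +/- %g nm)",
                   names(centres)[i], ctr, window_nm))
    j <- which(sel)[which.max(spectrum$intensities[sel])]
    list(amplitude = spectrum$intensities[j],
         wavelength_nm = spectrum$wavelengths_nm[j])
  })
  names(out) <- names(centres)
  out$t_minutes <- spectrum$t_minutes
  class(out) <- "fluorophore_amplitudes"
  out
}

#' @export
print.fluorophore_amplitudes <- function(x, ...) {
  for (nm in setdiff(names(x), "t_minutes"))
    cat(sprintf("%8s: %.4g a.u. at %.0f nm\n",
                nm, x[[nm]]$amplitude, x[[nm]]$wavelength_nm))
  invisible(x)
}

#' Optical redox ratio index
#'
#' Ratio of the NAD(P)H to the FAD+ fluorescence peak amplitude, a proxy for
#' the mitochondrial redox state (balance between the reduced NAD(P)H and
#' oxidised FAD+ coenzymes).
#'
#' @param amps a `fluorophore_amplitudes` object from [peak_amplitudes()].
#' @return dimensionless ratio NAD(P)H / FAD+.
#' @export
rr_index <- function(amps) {
  stopifnot(inherits(amps, "fluorophore_amplitudes"))
  if (amps$fad$amplitude <= 0)
    stop("FAD+ amplitude must be positive to form the redox ratio")
  amps$nadph$amplitude / amps$fad$amplitude
}

#' Elastin-normalised NAD(P)H fluorescence
#'
#' NAD(P)H peak amplitude divided by the elastin peak amplitude. The elastin
#' peak acts as an internal reference, reducing blood-volume artefacts that
#' scale the whole emission spectrum.
#'
#' @inheritParams rr_index
#' @return dimensionless ratio NAD(P)H / elastin.
#' @export
nadph_normalised <- function(amps) {
  stopifnot(inherits(amps, "fluorophore_amplitudes"))
  if (amps$elastin$amplitude <= 0)
    stop("elastin amplitude must be positive for normalisation")
  amps$nadph$amplitude / amps$elastin$amplitude
}

#' Biomarker time series from a sequence of emission spectra
#'
#' Applies [peak_amplitudes()], [rr_index()] and [nadph_normalised()] to each
#' spectrum of a recording (typically 20 spectra in 20 minutes, one per
#' minute).
#'
#' @param spectra list of [emission_spectrum()] objects with strictly
#'   increasing, non-missing timestamps.
#' @param window_nm search half-width passed to [peak_amplitudes()].
#' @return data frame with one row per spectrum: `t_minutes`,
#'   `elastin_amp`, `nadph_amp`, `fad_amp`, `rr_index`, `nadph_normalised`.
#' @export
metabolic_series <- function(spectra, window_nm = 10) {
  if (length(spectra) < 2L)
    stop("need at least 2 spectra to form a time series")
  tt <- vapply(spectra, function(s) s$t_minutes, numeric(1))
  if (anyNA(tt)) stop("all spectra need timestamps")
  if (any(diff(tt) <= 0)) {
    bad <- tt[which(diff(tt) <= 0)[1] + 1L]
    stop(sprintf("timestamps must be strictly increasing (offending t = %g min)", bad))
  }
  rows <- lapply(spectra, function(s) {
    a <- tryCatch(peak_amplitudes(s, window_nm = window_nm), error = function(e)
      stop(sprintf("spectrum at t = %g min: %s", s$t_minutes, conditionMessage(e)),
           call. = FALSE))
    data.frame(t_minutes = s$t_minutes,
               elastin_amp = a$elastin$amplitude,
               nadph_amp = a$nadph$amplitude,
               fad_amp = a$fad$amplitude,
               rr_index = rr_index(a),
               nadph_normalised = nadph_normalised(a))
  })
  do.call(rbind, rows)
}

#' Haemoglobin extinction table
#'
#' Two-column table of molar extinction coefficients of oxy- and
#' deoxyhaemoglobin on a wavelength grid, used by [estimate_so2()]. The
#' default is a nominal two-wavelength table at 530 nm (green) and 630 nm
#' (red) with adult-haemoglobin literature values (cm^-1 / M); the probe the
#' analysis targets uses green and red lasers at close-by wavelengths.
#' Concentrations recovered with it are relative, which is all the SO2
#' percentage needs. Users may supply any table on any grid.
#'
#' @param wavelengths_nm wavelength grid (nm).
#' @param eps_oxy molar extinction of oxyhaemoglobin at each wavelength.
#' @param eps_deoxy molar extinction of deoxyhaemoglobin at each wavelength.
#' @return object of class `extinction_table`.
#' @export
extinction_table <- function(wavelengths_nm = c(530, 630),
                             eps_oxy = c(39036.7, 610.0),
                             eps_deoxy = c(39437.2, 5148.8)) {
  wavelengths_nm <- as.numeric(wavelengths_nm)
  eps_oxy <- as.numeric(eps_oxy)
  eps_deoxy <- as.numeric(eps_deoxy)
  n <- length(wavelengths_nm)
  if (length(eps_oxy) != n || length(eps_deoxy) != n)
    stop("extinction columns must match the wavelength grid")
  if (any(eps_oxy <= 0) || any(eps_deoxy <= 0))
    stop("extinction coefficients must be positive")
  structure(list(wavelengths_nm = wavelengths_nm,
                 eps_oxy = eps_oxy, eps_deoxy = eps_deoxy),
            class = "extinction_table")
}

#' Tissue oxygen saturation from differential light absorption
#'
#' Unmixes an observed absorption spectrum into relative oxy- and
#' deoxyhaemoglobin concentrations via the Beer-Lambert law
#' `mu_a(lambda) = sum_i eps_i(lambda) * C_i`, solved in least squares, and
#' reports the percentage saturation `SO2 = 100 * [oxyHb] / [oxyHb + deoxyHb]`.
#' Negative least-squares concentrations are clipped to zero and flagged.
#'
#' @param wavelengths_nm wavelengths of the observation (must all be present
#'   in the extinction table).
#' @param mu_a absorption coefficient at each wavelength (units consistent
#'   with the table).
#' @param table an [extinction_table()].
#' @return object of class `so2_estimate`: list with `c_oxy`, `c_deoxy`
#'   (relative molar units), `so2_percent`, and flags `clipped` /
#'   `undefined` (the latter when both concentrations are zero, in which
#'   case `so2_percent` is `NA`).
#' @export
estimate_so2 <- function(wavelengths_nm, mu_a, table = extinction_table()) {
  stopifnot(inherits(table, "extinction_table"))
  wavelengths_nm <- as.numeric(wavelengths_nm)
  mu_a <- as.numeric(mu_a)
  if (length(wavelengths_nm) != length(mu_a))
    stop("mu_a must match the observation wavelengths")
  if (length(wavelengths_nm) < 2L)
    stop("need at least 2 wavelengths to separate two absorbers")
  if (any(mu_a < 0)) stop("absorption coefficients must be non-negative")
  idx <- match(wavelengths_nm, table$wavelengths_nm)
  if (anyNA(idx))
    stop(sprintf("wavelength %g nm is not in the extinction table",
                 wavelengths_nm[which(is.na(idx))[1]]))
  E <- cbind(oxy = table$eps_oxy[idx], deoxy = table$eps_deoxy[idx])
  # collinear columns make the unmixing ill-posed
  if (rcond_2col(E) < 1e-10)
    stop("extinction columns are (near-)collinear; SO2 unmixing is ill-conditioned")
  beta <- qr.solve(E, mu_a)
  clipped <- any(beta < 0)
  beta <- pmax(beta, 0)
  tot <- sum(beta)
  structure(list(c_oxy = beta[["oxy"]], c_deoxy = beta[["deoxy"]],
                 so2_percent = if (tot > 0) 100 * beta[["oxy"]] / tot else NA_real_,
                 clipped = clipped, undefined = tot <= 0),
            class = "so2_estimate")
}

#' @export
print.so2_estimate <- function(x, ...) {
  if (x$undefined) {
    cat("<so2_estimate> undefined (both concentrations zero)\n")
  } else {
    cat(sprintf("<so2_estimate> SO2 = %.1f%%  (c_oxy %.4g, c_deoxy %.4g%s)\n",
                x$so2_percent, x$c_oxy, x$c_deoxy,
                if (x$clipped) ", clipped" else ""))
  }
  invisible(x)
}

# reciprocal condition number of an n x 2 matrix via its 2x2 Gram matrix
rcond_2col <- function(E) {
  G <- crossprod(E)
  tr <- G[1, 1] + G[2, 2]
  dt <- G[1, 1] * G[2, 2] - G[1, 2]^2
  disc <- sqrt(max(tr^2 / 4 - dt, 0))
  l1 <- tr / 2 + disc
  l2 <- tr / 2 - disc
  if (l1 <= 0) return(0)
  sqrt(max(l2, 0) / l1)
}

#' Forward Beer-Lambert absorption model
#'
#' Computes `mu_a(lambda) = c_oxy * eps_oxy + c_deoxy * eps_deoxy` on the
#' table's grid (or a subset). Used to simulate reflectance observations
#' with a known saturation and in round-trip validation of [estimate_so2()].
#'
#' @param c_oxy,c_deoxy non-negative relative concentrations.
#' @param table an [extinction_table()].
#' @param wavelengths_nm subset of the table grid (default: whole grid).
#' @return numeric vector of absorption coefficients.
#' @export
forward_absorption <- function(c_oxy, c_deoxy, table = extinction_table(),
                               wavelengths_nm = table$wavelengths_nm) {
  stopifnot(inherits(table, "extinction_table"), c_oxy >= 0, c_deoxy >= 0)
  idx <- match(wavelengths_nm, table$wavelengths_nm)
  if (anyNA(idx)) stop("requested wavelength not in the table")
  c_oxy * table$eps_oxy[idx] + c_deoxy * table$eps_deoxy[idx]
}
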