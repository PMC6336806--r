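#' Read a two-column signal file
#'
#' Delimited text with columns `t_seconds,value` (header optional,
#' delimiter sniffed among comma, tab and whitespace). If the sample times
#' are uniform the result is a [uniform_series()], otherwise an
#' [irregular_series()].
#'
#' @param path file path.
#' @param label signal label (default: file name without extension).
#' @return a [uniform_series()] or [irregular_series()].
#' @export
read_signal_file <- function(path, label = NULL) {
  d <- read_delim_sniff(path, c("t_seconds", "value"))
  if (is.null(label)) label <- sub("\\.[^.]*$", "", basename(path))
  dt <- diff(d$t_seconds)
  if (length(dt) && max(abs(dt - dt[1])) < 1e-6 * dt[1])
    uniform_series(d$value, fs_hz = 1 / dt[1], t0_seconds = d$t_seconds[1],
                   label = label)
  else irregular_series(d$t_seconds, d$value, label = label)
}

#' Write a uniform series as a two-column signal file
#'
#' @param series a [uniform_series()].
#' @param path output path (CSV: `t_seconds,value`).
#' @export
write_signal_file <- function(series, path) {
  stopifnot(inherits(series, "uniform_series"))
  utils::write.csv(data.frame(t_seconds = series_times(series),
                              value = series$values),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read one emission-spectrum file
#'
#' Delimited text with columns `wavelength_nm,intensity`.
#'
#' @param path file path.
#' @param t_minutes acquisition timestamp (min).
#' @return an [emission_spectrum()].
#' @export
read_spectrum_file <- function(path, t_minutes = NA_real_) {
  d <- read_delim_sniff(path, c("wavelength_nm", "intensity"))
  emission_spectrum(d$wavelength_nm, d$intensity, t_minutes = t_minutes)
}

#' Read a spectral time series through a manifest
#'
#' The manifest is a CSV with columns `file,t_minutes`; paths are resolved
#' relative to the manifest location.
#'
#' @param manifest_path manifest CSV path.
#' @return list of [emission_spectrum()]s ordered by timestamp.
#' @export
read_spectra_manifest <- function(manifest_path) {
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  if (!all(c("file", "t_minutes") %in% names(man)))
    stop("manifest needs columns 'file' and 't_minutes'")
  man <- man[order(man$t_minutes), ]
  base <- dirname(manifest_path)
  lapply(seq_len(nrow(man)), function(i)
    read_spectrum_file(file.path(base, man$file[i]), man$t_minutes[i]))
}

#' Write a spectral time series with its manifest
#'
#' @param spectra list of [emission_spectrum()]s.
#' @param dir output directory (created if missing).
#' @return path of the written manifest.
#' @export
write_spectra <- function(spectra, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(length(spectra))
  for (i in seq_along(spectra)) {
    files[i] <- sprintf("spectrum_%03d.csv", i)
    utils::write.csv(data.frame(wavelength_nm = spectra[[i]]$wavelengths_nm,
                                intensity = spectra[[i]]$intensities),
                     file.path(dir, files[i]), row.names = FALSE)
  }
  man <- file.path(dir, "manifest.csv")
  utils::write.csv(data.frame(
    file = files,
    t_minutes = vapply(spectra, function(s) s$t_minutes, numeric(1))),
    man, row.names = FALSE)
  invisible(man)
}

#' Read an extinction table from CSV
#'
#' Columns `wavelength_nm,eps_oxy,eps_deoxy`.
#'
#' @param path CSV path.
#' @return an [extinction_table()].
#' @export
read_extinction_csv <- function(path) {
  d <- utils::read.csv(path)
  need <- c("wavelength_nm", "eps_oxy", "eps_deoxy")
  if (!all(need %in% names(d)))
    stop("extinction CSV needs columns wavelength_nm, eps_oxy, eps_deoxy")
  extinction_table(d$wavelength_nm, d$eps_oxy, d$eps_deoxy)
}

# sniff delimiter and presence of a header from the first line
read_delim_sniff <- function(path, col_names) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first)) "," else if (grepl("\t", first)) "\t" else ""
  header <- grepl("[A-Za-z]", sub("^#.*", "", first))
  d <- utils::read.table(path, sep = sep, header = header,
                         comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(d) < 2L) stop(sprintf("'%s': need two columns", path))
  d <- d[, 1:2]
  names(d) <- col_names
  d
}

# stable short hash of a configuration (FNV-1a over its deparsed form)
config_hash <- function(config) {
  s <- paste(deparse(config), collapse = "")
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    h <- bitwXor(h, b)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%08x", h)
}

#' Write a metrics table as CSV with a configuration stamp
#'
#' RFC-4180 CSV with a single header row, preceded by a comment line
#' `# config_hash=<hash>` identifying the configuration that produced it.
#'
#' @param df data frame to write.
#' @param path output path.
#' @param config the configuration object to stamp.
#' @export
write_metrics_csv <- function(df, path, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(config))
    writeLines(sprintf("# config_hash=%s", config_hash(config)), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a metrics CSV written by [write_metrics_csv()]
#'
#' @param path CSV path.
#' @return data frame; the config hash (if present) is attached as the
#'   `config_hash` attribute.
#' @export
read_metrics_csv <- function(path) {
  first <- readLines(path, n = 1L)
  hash <- if (startsWith(first, "# config_hash="))
    sub("# config_hash=", "", first) else NULL
  d <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  attr(d, "config_hash") <- hash
  d
}

#' Write all outputs of a study analysis
#'
#' Emits `metrics.csv`, `comparisons.csv`, `correlations.csv`,
#' `normality.csv`, `table1.csv` and a plain-text `report.txt` into a
#' directory. Existing files are only replaced when `force = TRUE`.
#'
#' @param study a [run_study()] result.
#' @param dir output directory.
#' @param force overwrite existing outputs.
#' @return `dir`, invisibly.
#' @export
write_study_outputs <- function(study, dir, force = FALSE) {
  stopifnot(inherits(study, "study_analysis"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tgt <- file.path(dir, c("metrics.csv", "comparisons.csv",
                          "correlations.csv", "normality.csv",
                          "table1.csv", "report.txt"))
  if (!force && any(file.exists(tgt)))
    stop("output files exist; use force = TRUE to overwrite")
  cfg <- study$config
  write_metrics_csv(study$metrics, tgt[1], cfg)
  if (!is.null(study$comparisons)) write_metrics_csv(study$comparisons, tgt[2], cfg)
  if (!is.null(study$correlations)) write_metrics_csv(study$correlations, tgt[3], cfg)
  if (!is.null(study$normality)) write_metrics_csv(study$normality, tgt[4], cfg)
  if (!is.null(study$table1)) write_metrics_csv(study$table1, tgt[5], cfg)
  con <- file(tgt[6], "w")
  sink(con)
  on.exit({ sink(); close(con) })
  print(study)
  if (!is.null(study$table1)) summary(study)
  if (!is.null(study$comparisons)) {
    cat(sprintf("\n%d t-tests performed (no multiplicity correction applied).\n",
                nrow(study$comparisons)))
    cat("Significant comparisons (p < 0.05):\n")
    print(study$comparisons[study$comparisons$significant,
                            c("variable", "contrast", "group", "window", "t", "p")],
          row.names = FALSE)
  }
  invisible(dir)
}
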