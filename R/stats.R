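#' Normality screen for study variables
#'
#' Shapiro-Wilk test per variable of a subject-metrics table. Variables
#' failing the test (p < 0.05) are flagged, not excluded: the downstream
#' comparisons stay parametric, the flag is a caution for the reader.
#' Constant vectors and groups with fewer than 3 values are flagged
#' untestable.
#'
#' @param metrics data frame of subject metrics (one row per subject and
#'   window; see [subject_metrics()]).
#' @param variables character vector of column names to screen; default:
#'   every numeric column except identifiers.
#' @return data frame: `variable`, `n`, `W`, `p`, `untestable`,
#'   `non_normal`.
#' @export
normality_gate <- function(metrics, variables = NULL) {
  if (is.null(variables))
    variables <- setdiff(names(metrics)[vapply(metrics, is.numeric, TRUE)],
                         c("subject", "group", "window"))
  rows <- lapply(variables, function(v) {
    x <- metrics[[v]]
    x <- x[is.finite(x)]
    if (length(x) < 3L) {
      warning(sprintf("variable '%s': fewer than 3 values, normality not tested", v))
      return(data.frame(variable = v, n = length(x), W = NA_real_,
                        p = NA_real_, untestable = TRUE, non_normal = NA))
    }
    if (stats::sd(x) == 0)
      return(data.frame(variable = v, n = length(x), W = NA_real_,
                        p = NA_real_, untestable = TRUE, non_normal = NA))
    sw <- stats::shapiro.test(x)
    data.frame(variable = v, n = length(x), W = unname(sw$statistic),
               p = sw$p.value, untestable = FALSE,
               non_normal = sw$p.value < 0.05)
  })
  do.call(rbind, rows)
}

#' Baseline-vs-stimulus and between-group comparisons
#'
#' Two-sided t-tests in the two contrasts of a baseline/stimulus two-group
#' design: `"within"` pairs each subject's baseline value with its stimulus
#' value (paired t-test, one group at a time); `"between"` compares the two
#' groups inside one window (unpaired Student t-test with pooled variance
#' by default; Welch available).
#'
#' @param metrics data frame with columns `subject`, `group`, `window` and
#'   the variable.
#' @param variable column name to compare.
#' @param contrast `"within"` or `"between"`.
#' @param group group label (required for `"within"`).
#' @param window window label (required for `"between"`).
#' @param windows the two window labels, baseline first.
#' @param groups the two group labels (default: first two in the data).
#' @param var_equal pooled-variance t-test for the between contrast
#'   (default `TRUE`).
#' @return one-row data frame with per-side means, SDs and n, the t
#'   statistic, degrees of freedom, p value and a `significant` flag
#'   (p < 0.05).
#' @export
compare_metrics <- function(metrics, variable,
                            contrast = c("within", "between"),
                            group = NULL, window = NULL,
                            windows = c("baseline", "pe"),
                            groups = NULL, var_equal = TRUE) {
  contrast <- match.arg(contrast)
  if (!variable %in% names(metrics)) stop(sprintf("no variable '%s'", variable))
  if (contrast == "within") {
    if (is.null(group)) stop("the within contrast needs a group")
    d <- metrics[metrics$group == group, ]
    a <- d[d$window == windows[1], c("subject", variable)]
    b <- d[d$window == windows[2], c("subject", variable)]
    m <- merge(a, b, by = "subject", suffixes = c("_1", "_2"))
    if (nrow(m) < 2L || nrow(m) != nrow(a) || nrow(m) != nrow(b))
      stop("paired contrast needs matched subjects in both windows")
    x <- m[[paste0(variable, "_1")]]
    y <- m[[paste0(variable, "_2")]]
    if (stats::sd(x - y) == 0) {
      tt <- list(statistic = c(t = 0), parameter = c(df = nrow(m) - 1),
                 p.value = 1)
      degenerate <- TRUE
    } else {
      tt <- stats::t.test(x, y, paired = TRUE)
      degenerate <- FALSE
    }
    out <- data.frame(variable = variable, contrast = "within",
                      group = group, window = NA_character_,
                      side1 = windows[1], side2 = windows[2],
                      mean1 = mean(x), sd1 = stats::sd(x), n1 = length(x),
                      mean2 = mean(y), sd2 = stats::sd(y), n2 = length(y),
                      t = unname(tt$statistic), df = unname(tt$parameter),
                      p = tt$p.value)
    out$degenerate <- degenerate
  } else {
    if (is.null(window)) stop("the between contrast needs a window")
    d <- metrics[metrics$window == window, ]
    if (is.null(groups)) groups <- unique(d$group)[1:2]
    x <- d[d$group == groups[1], variable, drop = TRUE]
    y <- d[d$group == groups[2], variable, drop = TRUE]
    if (length(x) < 2L || length(y) < 2L)
      stop("between contrast needs at least 2 subjects per group")
    tt <- stats::t.test(x, y, var.equal = var_equal)
    out <- data.frame(variable = variable, contrast = "between",
                      group = paste(groups, collapse = " vs "),
                      window = window,
                      side1 = groups[1], side2 = groups[2],
                      mean1 = mean(x), sd1 = stats::sd(x), n1 = length(x),
                      mean2 = mean(y), sd2 = stats::sd(y), n2 = length(y),
                      t = unname(tt$statistic), df = unname(tt$parameter),
                      p = tt$p.value)
    out$degenerate <- FALSE
  }
  out$significant <- !is.na(out$p) & out$p < 0.05
  out
}

#' Pearson correlation with the relevance rule
#'
#' Pearson correlation between two study variables, either pooled over
#' both windows (each subject contributes a baseline row and a stimulus
#' row, so n is twice the number of subjects) or inside one window. A
#' correlation is flagged *relevant* when `p <= 0.05` and `|r| > 0.5`.
#'
#' @param metrics subject-metrics data frame.
#' @param var_x,var_y column names.
#' @param group restrict to one group (`NULL` = all rows).
#' @param subset `"pooled"`, `"baseline"` or `"pe"`.
#' @return one-row data frame: `var_x`, `var_y`, `group`, `subset`, `n`,
#'   `r`, `p`, `relevant`.
#' @export
correlate_metrics <- function(metrics, var_x, var_y, group = NULL,
                              subset = c("pooled", "baseline", "pe")) {
  subset <- match.arg(subset)
  d <- metrics
  if (!is.null(group)) d <- d[d$group == group, ]
  if (subset != "pooled") d <- d[d$window == subset, ]
  x <- d[[var_x]]
  y <- d[[var_y]]
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("correlation needs at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: a variable has zero variance")
  ct <- stats::cor.test(x, y, method = "pearson")
  r <- unname(ct$estimate)
  data.frame(var_x = var_x, var_y = var_y,
             group = if (is.null(group)) "all" else group,
             subset = subset, n = length(x), r = r, p = ct$p.value,
             relevant = ct$p.value <= 0.05 & abs(r) > 0.5)
}

#' Mean-and-SD summary table
#'
#' Mean +/- standard deviation of every variable per group and window, in
#' the familiar one-row-per-variable layout of a clinical summary table.
#'
#' @param metrics subject-metrics data frame.
#' @param variables columns to summarise (default: all numeric).
#' @return data frame: `variable`, then one `mean` / `sd` / `n` triple per
#'   group x window cell, plus a `formatted` data frame attribute with
#'   "mean +/- sd" strings.
#' @export
summary_table <- function(metrics, variables = NULL) {
  if (is.null(variables))
    variables <- setdiff(names(metrics)[vapply(metrics, is.numeric, TRUE)],
                         c("subject", "group", "window"))
  cells <- expand.grid(group = unique(metrics$group),
                       window = unique(metrics$window),
                       stringsAsFactors = FALSE)
  rows <- lapply(variables, function(v) {
    row <- data.frame(variable = v)
    for (i in seq_len(nrow(cells))) {
      d <- metrics[metrics$group == cells$group[i] &
                     metrics$window == cells$window[i], v, drop = TRUE]
      d <- d[is.finite(d)]
      tag <- paste(cells$group[i], cells$window[i], sep = ".")
      row[[paste0(tag, ".mean")]] <- if (length(d)) mean(d) else NA_real_
      row[[paste0(tag, ".sd")]] <- if (length(d) > 1) stats::sd(d) else NA_real_
      row[[paste0(tag, ".n")]] <- length(d)
      if (length(d) == 1L)
        warning(sprintf("variable '%s', %s/%s: single value, SD undefined",
                        v, cells$group[i], cells$window[i]))
    }
    row
  })
  out <- do.call(rbind, rows)
  fmt <- data.frame(variable = out$variable)
  for (i in seq_len(nrow(cells))) {
    tag <- paste(cells$group[i], cells$window[i], sep = ".")
    fmt[[tag]] <- ifelse(
      is.na(out[[paste0(tag, ".mean")]]), "",
      sprintf("%.3g ± %.2g", out[[paste0(tag, ".mean")]],
              out[[paste0(tag, ".sd")]]))
  }
  attr(out, "formatted") <- fmt
  out
}
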