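# Operator performance statistics: distance metrics, correlations,
# Bland-Altman agreement, Kruskal-Wallis inter-rater test, Likert
# descriptives.  Standard tests are delegated to base R (cor.test,
# kruskal.test); only the thin domain wrappers live here.

#' Per-participant puncture distance metrics
#'
#' Straight-line (chordal) 3D Euclidean distance from each recorded puncture
#' to the maximum-GII site and to the FO centroid, summarized per
#' participant as mean and SD.
#'
#' @param records data frame with columns `participant`, `experience_years`,
#'   `trial`, `x`, `y`, `z`, `time_s` (as read by [read_punctures()]).
#' @param argmax_point 3D coordinates of the maximum-GII site (mm).
#' @param centroid 3D coordinates of the FO centroid (mm).
#' @return Data frame, one row per participant (input order):
#'   `participant`, `experience_years`, `n`, `mean_dist_gii`, `sd_dist_gii`,
#'   `mean_dist_centroid`, `sd_dist_centroid`.  SD is the sample SD, 0 for a
#'   single trial.
#' @export
distance_metrics <- function(records, argmax_point, centroid) {
  records <- validate_punctures(records)
  argmax_point <- assert_point3(argmax_point, "argmax_point")
  centroid <- assert_point3(centroid, "centroid")
  pts <- as.matrix(records[, c("x", "y", "z")])
  d_gii <- sqrt(rowSums((pts - matrix(argmax_point, nrow(pts), 3, byrow = TRUE))^2))
  d_ctr <- sqrt(rowSums((pts - matrix(centroid, nrow(pts), 3, byrow = TRUE))^2))
  ids <- unique(records$participant)
  out <- do.call(rbind, lapply(ids, function(id) {
    sel <- records$participant == id
    sd0 <- function(v) if (sum(sel) > 1L) stats::sd(v) else 0
    data.frame(participant = id,
               experience_years = records$experience_years[sel][1L],
               n = sum(sel),
               mean_dist_gii = mean(d_gii[sel]), sd_dist_gii = sd0(d_gii[sel]),
               mean_dist_centroid = mean(d_ctr[sel]),
               sd_dist_centroid = sd0(d_ctr[sel]))
  }))
  rownames(out) <- NULL
  out
}

validate_punctures <- function(records) {
  need <- c("participant", "experience_years", "trial", "x", "y", "z", "time_s")
  if (!is.data.frame(records) || nrow(records) == 0L)
    fg_validation_error("puncture records must be a nonempty data frame")
  miss <- setdiff(need, names(records))
  if (length(miss))
    fg_validation_error(paste("puncture records missing columns:",
                              paste(miss, collapse = ", ")))
  if (any(!is.finite(records$time_s)) || any(records$time_s <= 0))
    fg_validation_error("procedural times must be positive")
  records
}

#' Pearson correlation with two-sided t-test p-value
#'
#' @param x,y equal-length numeric vectors (n >= 3), each with nonzero
#'   variance.
#' @return Object of class `fg_correlation`: `r`, `p` (two-sided,
#'   t-distribution with n - 2 df), `n`.
#' @export
correlate <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y) || length(x) < 3L)
    fg_validation_error("x and y must have equal length >= 3")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    fg_domain_error("degenerate input: zero variance")
  ct <- stats::cor.test(x, y, method = "pearson")
  structure(list(r = unname(ct$estimate), p = ct$p.value, n = length(x)),
            class = "fg_correlation")
}

#' @export
print.fg_correlation <- function(x, ...) {
  cat(sprintf("Pearson r = %.3f (p = %.3g, n = %d)\n", x$r, x$p, x$n))
  invisible(x)
}

#' Bland-Altman agreement of paired measurements
#'
#' Differences `a - b`; bias is their mean, limits of agreement
#' bias +/- 1.96 * SD (sample SD), and `pct_within` the percentage of the
#' same pairs falling inside the limits.
#'
#' @param a,b paired measurements (mm), length >= 2.
#' @return Object of class `fg_agreement`: `bias`, `sd_diff`, `loa_low`,
#'   `loa_high`, `pct_within`, `n`, `diffs`, `means`.
#' @export
bland_altman <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b) || length(a) < 2L)
    fg_validation_error("need >= 2 pairs of equal length")
  d <- a - b
  bias <- mean(d)
  s <- stats::sd(d)
  loa <- bias + c(-1, 1) * 1.96 * s
  within <- if (s == 0) rep(TRUE, length(d)) else d >= loa[1] & d <= loa[2]
  structure(list(bias = bias, sd_diff = s, loa_low = loa[1], loa_high = loa[2],
                 pct_within = 100 * mean(within), n = length(d),
                 diffs = d, means = (a + b) / 2),
            class = "fg_agreement")
}

#' @export
print.fg_agreement <- function(x, ...) {
  cat(sprintf("Bland-Altman: bias %.3f mm, LoA [%.3f, %.3f] mm, %.1f%% within (n = %d)\n",
              x$bias, x$loa_low, x$loa_high, x$pct_within, x$n))
  invisible(x)
}

#' @export
plot.fg_agreement <- function(x, ...) {
  graphics::plot(x$means, x$diffs, pch = 16, col = "grey30",
                 xlab = "mean of pair (mm)", ylab = "difference (mm)",
                 main = "Bland-Altman agreement", ...)
  graphics::abline(h = c(x$bias, x$loa_low, x$loa_high),
                   lty = c(1, 2, 2), col = c("black", "red2", "red2"))
  invisible(x)
}

#' Kruskal-Wallis rank test across groups
#'
#' Tie-corrected H statistic with a chi-square reference (k - 1 df), via
#' [stats::kruskal.test()].  The degenerate all-identical input returns
#' H = 0, p = 1.
#'
#' @param groups list of >= 2 numeric vectors (each nonempty, >= 5 values in
#'   total).
#' @return List with `H`, `p`, `df`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    fg_validation_error("groups must be a list of >= 2 numeric vectors")
  if (any(lengths(groups) == 0L) || sum(lengths(groups)) < 5L)
    fg_validation_error("each group needs >= 1 value and >= 5 values in total")
  values <- unlist(groups, use.names = FALSE)
  if (length(unique(values)) == 1L)
    return(list(H = 0, p = 1, df = length(groups) - 1L))
  g <- factor(rep(seq_along(groups), lengths(groups)))
  kt <- stats::kruskal.test(values, g)
  list(H = unname(kt$statistic), p = kt$p.value, df = unname(kt$parameter))
}

#' Likert questionnaire descriptives
#'
#' Per-question mean and SD of 1-5 agreement scores.  Default SD is the
#' population SD (divisor n), the convention under which small-panel splits
#' such as scores 4 and 5 summarize as 4.50 +/- 0.50; the sample convention
#' is switchable.
#'
#' @param responses data frame with columns `question` and `score` (integer
#'   1-5); a `participant` column is allowed and ignored.
#' @param sd_type `"population"` (default) or `"sample"`.
#' @return Data frame `question`, `n`, `mean`, `sd`, `label`
#'   (formatted "m +/- s").
#' @export
likert_summary <- function(responses, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  if (!is.data.frame(responses) ||
      !all(c("question", "score") %in% names(responses)))
    fg_validation_error("responses needs columns 'question' and 'score'")
  sc <- responses$score
  if (any(!is.finite(sc)) || any(sc != round(sc)) || any(sc < 1 | sc > 5))
    fg_validation_error("scores must be integers in 1..5")
  qs <- unique(responses$question)
  out <- do.call(rbind, lapply(qs, function(q) {
    v <- sc[responses$question == q]
    s <- if (sd_type == "population") sqrt(mean((v - mean(v))^2))
         else if (length(v) > 1L) stats::sd(v) else 0
    data.frame(question = q, n = length(v), mean = mean(v), sd = s,
               label = sprintf("%.2f ± %.2f", mean(v), s))
  }))
  rownames(out) <- NULL
  out
}

#' Read puncture records from CSV
#'
#' Expected columns: `participant`, `experience_years`, `trial`, `x`, `y`,
#' `z`, `time_s` (coordinates in mm, time in seconds).
#' @param path CSV path.
#' @return Validated data frame.
#' @export
read_punctures <- function(path) {
  if (!file.exists(path)) fg_resolution_error(sprintf("file not found: '%s'", path))
  validate_punctures(utils::read.csv(path))
}

#' Read paired caliper/STL measurements from CSV
#'
#' Expected columns: `feature`, `researcher`, `stl_mm`, `physical_mm`.
#' @param path CSV path.
#' @return Data frame.
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) fg_resolution_error(sprintf("file not found: '%s'", path))
  df <- utils::read.csv(path)
  need <- c("feature", "researcher", "stl_mm", "physical_mm")
  miss <- setdiff(need, names(df))
  if (length(miss))
    fg_validation_error(paste("measurements missing columns:",
                              paste(miss, collapse = ", ")))
  df
}

#' Read Likert responses from CSV
#'
#' Expected columns: `participant`, `question`, `score`.
#' @param path CSV path.
#' @return Data frame.
#' @export
read_likert <- function(path) {
  if (!file.exists(path)) fg_resolution_error(sprintf("file not found: '%s'", path))
  df <- utils::read.csv(path)
  miss <- setdiff(c("participant", "question", "score"), names(df))
  if (length(miss))
    fg_validation_error(paste("likert table missing columns:",
                              paste(miss, collapse = ", ")))
  df
}
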