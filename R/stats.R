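#' Paired per-subject measurements
#'
#' @param subject_ids subject labels.
#' @param baseline,condition numeric vectors of equal length (>= 2), e.g.
#'   FCD at healthy baseline and during hemorrhage.
#' @return list of class `paired_measurements`.
#' @export
paired_measurements <- function(subject_ids, baseline, condition) {
  n <- length(baseline)
  if (n < 2 || length(condition) != n || length(subject_ids) != n)
    stop("shape error: need equal-length vectors of length >= 2", call. = FALSE)
  structure(list(subject_ids = subject_ids, baseline = as.numeric(baseline),
                 condition = as.numeric(condition)),
            class = "paired_measurements")
}

#' Mean and sample standard deviation
#'
#' @param values numeric vector, length >= 2.
#' @return named vector `c(mean, sd)`; `sd` uses the `n - 1` denominator.
#' @export
summary_stats <- function(values) {
  if (length(values) < 2)
    stop("parameter error: need at least 2 values", call. = FALSE)
  c(mean = mean(values), sd = sd(values))
}

#' Paired t-test on baseline-versus-condition measurements
#'
#' Tests the hypothesis of zero mean within-subject difference
#' `d_i = baseline_i - condition_i`: `t = mean(d) / (sd(d) / sqrt(n))` with
#' `n - 1` degrees of freedom and a two-sided p-value.
#'
#' @param pm a [paired_measurements()].
#' @return list of class `ttest_result`: `t`, `df`, `p_two_sided`,
#'   `mean_diff`, `sd_diff`.
#' @export
paired_t <- function(pm) {
  d <- pm$baseline - pm$condition
  n <- length(d)
  sdd <- sd(d)
  if (sdd == 0)
    stop("degenerate-test error: zero variance of differences", call. = FALSE)
  tval <- mean(d) / (sdd / sqrt(n))
  df <- n - 1L
  structure(list(t = tval, df = df, p_two_sided = 2 * pt(-abs(tval), df),
                 mean_diff = mean(d), sd_diff = sdd),
            class = "ttest_result")
}

#' @export
print.ttest_result <- function(x, ...) {
  cat(sprintf("paired t-test: t(%d) = %.2f, p = %.3g, mean diff = %.3g (sd %.3g)\n",
              x$df, x$t, x$p_two_sided, x$mean_diff, x$sd_diff))
  invisible(x)
}

#' Bland-Altman agreement analysis
#'
#' @param a,b paired measurements from two methods, equal length >= 2.
#' @return list: `bias` (mean of `a - b`), `lower_loa`, `upper_loa`
#'   (bias -/+ 1.96 SD of the differences), and `points` (data.frame of
#'   per-pair means and differences, ready for plotting).
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2)
    stop("shape error: need equal-length vectors of length >= 2", call. = FALSE)
  d <- a - b
  bias <- mean(d)
  s <- sd(d)
  list(bias = bias, lower_loa = bias - 1.96 * s, upper_loa = bias + 1.96 * s,
       points = data.frame(mean = (a + b) / 2, diff = d))
}

#' Read a per-subject FCD table
#'
#' Reads a CSV with columns `subject`, `baseline_area`, `baseline_length`,
#' `hemorrhage_area`, `hemorrhage_length` (the layout of the packaged
#' study tables, see `system.file("extdata", package = "capdens")`) and
#' returns the requested measure as paired measurements.
#'
#' @param path CSV path.
#' @param measure `"area"` (percent) or `"length"` (mm/mm^2).
#' @return a [paired_measurements()].
#' @export
read_fcd_table <- function(path, measure = c("area", "length")) {
  measure <- match.arg(measure)
  tb <- read.csv(path)
  need <- c("subject", paste0(c("baseline_", "hemorrhage_"), measure))
  if (!all(need %in% names(tb)))
    stop("input-format error: missing columns ",
         paste(setdiff(need, names(tb)), collapse = ", "), call. = FALSE)
  paired_measurements(tb$subject,
                      tb[[paste0("baseline_", measure)]],
                      tb[[paste0("hemorrhage_", measure)]])
}
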