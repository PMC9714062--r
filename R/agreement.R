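#' Bland-Altman agreement between achieved and predicted vault
#'
#' Computes the standard agreement summary for paired measurements of the
#' same quantity: differences d = actual - predicted, their mean and
#' sample SD (n-1 denominator), the 95% confidence interval of the mean
#' difference (normal-theory, mean +/- 1.96 SD/sqrt(n)) and the 95%
#' limits of agreement (mean +/- 1.96 SD).
#'
#' @param actual Numeric vector of achieved vaults, um.
#' @param predicted Numeric vector of predicted vaults, um, same length.
#' @return An object of class `agreement_summary`: a list with `n`,
#'   `mean_diff`, `sd_diff`, `diff_range`, `quartiles` (25th/75th
#'   percentile of the differences, linear interpolation), `ci95`,
#'   `loa95` (all um).
#' @export
#' @examples
#' set.seed(1)
#' pred <- runif(50, 300, 700)
#' bland_altman(pred + rnorm(50, 6, 176), pred)
bland_altman <- function(actual, predicted) {
  if (!is.numeric(actual) || !is.numeric(predicted))
    stop("actual and predicted must be numeric")
  if (length(actual) != length(predicted))
    stop("actual and predicted must have equal length (",
         length(actual), " vs ", length(predicted), ")")
  if (length(actual) < 2L)
    stop("at least 2 paired observations are required")
  if (any(!is.finite(actual)) || any(!is.finite(predicted)))
    stop("actual and predicted must be finite")
  d <- actual - predicted
  m <- mean(d)
  s <- stats::sd(d)
  n <- length(d)
  structure(list(
    n = n,
    mean_diff = m,
    sd_diff = s,
    diff_range = range(d),
    quartiles = unname(stats::quantile(d, c(0.25, 0.75), type = 7)),
    ci95 = c(m - 1.96 * s / sqrt(n), m + 1.96 * s / sqrt(n)),
    loa95 = c(m - 1.96 * s, m + 1.96 * s)
  ), class = "agreement_summary")
}

#' 95% limits of agreement from a mean and SD of differences
#'
#' Reconstructs the limits of agreement `mean +/- 1.96 * sd` directly
#' from summary statistics, as printed in published tables.
#'
#' @param mean_diff Mean difference, um.
#' @param sd_diff Standard deviation of the differences, um.
#' @return Numeric vector `c(low, high)`, um, unrounded.
#' @export
#' @examples
#' round(loa_from_summary(6.43, 176.20))   # overall limits
loa_from_summary <- function(mean_diff, sd_diff) {
  stopifnot(is.numeric(mean_diff), is.numeric(sd_diff), sd_diff >= 0)
  c(mean_diff - 1.96 * sd_diff, mean_diff + 1.96 * sd_diff)
}

#' @export
print.agreement_summary <- function(x, digits = 2, ...) {
  cat(sprintf("Agreement (actual - predicted), n = %d eyes\n", x$n))
  cat(sprintf("  mean difference: %.*f um (SD %.*f)\n",
              digits, x$mean_diff, digits, x$sd_diff))
  cat(sprintf("  95%% CI of mean:  %.*f to %.*f um\n",
              digits, x$ci95[1], digits, x$ci95[2]))
  cat(sprintf("  95%% LoA:         %.*f to %.*f um\n",
              digits, x$loa95[1], digits, x$loa95[2]))
  invisible(x)
}

#' Per-stratum and pooled summary of predicted and actual vaults
#'
#' One row per stratum plus a pooled `overall` row (recomputed on all
#' records, not an average of the per-stratum rows), each giving n, mean,
#' SD and range of the predicted and the actual vault.
#'
#' @param records Data.frame with numeric `predicted_vault` and
#'   `actual_vault` columns.
#' @param stratum_key Name of the stratum column (default `"season"`);
#'   `NULL` for a pooled-only summary.
#' @return Data.frame, one row per stratum plus `overall`.
#' @export
summarize_vaults <- function(records, stratum_key = "season") {
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop("records must be a nonempty data.frame")
  for (col in c("predicted_vault", "actual_vault"))
    if (!is.numeric(records[[col]]))
      stop("records must carry numeric '", col, "'")
  strata <- if (is.null(stratum_key)) list() else
    split(records, records[[stratum_key]])
  one <- function(df, label) {
    data.frame(stratum = label, n = nrow(df),
               predicted_mean = mean(df$predicted_vault),
               predicted_sd = stats::sd(df$predicted_vault),
               predicted_min = min(df$predicted_vault),
               predicted_max = max(df$predicted_vault),
               actual_mean = mean(df$actual_vault),
               actual_sd = stats::sd(df$actual_vault),
               actual_min = min(df$actual_vault),
               actual_max = max(df$actual_vault),
               stringsAsFactors = FALSE)
  }
  rows <- lapply(names(strata), function(s) one(strata[[s]], s))
  rows <- c(rows, list(one(records, "overall")))
  do.call(rbind, rows)
}

#' Vault-category distribution by stratum
#'
#' Counts and percentages of low/normal/high vault per stratum, plus an
#' overall column obtained by summing the per-stratum counts. Percentages
#' are count / stratum n * 100, rounded to 2 decimals.
#'
#' @param records Data.frame with a `category` column (levels `low`,
#'   `normal`, `high`, as from [classify_vault()]).
#' @param stratum_key Name of the stratum column, or `NULL` for a pooled
#'   table only.
#' @return Data.frame with columns `stratum`, `category`, `count`,
#'   `percent`.
#' @export
distribution_table <- function(records, stratum_key = "season") {
  if (!is.data.frame(records) || !"category" %in% names(records))
    stop("records must carry a 'category' column")
  cat_levels <- c("low", "normal", "high")
  categ <- factor(records$category, levels = cat_levels)
  if (any(is.na(categ))) stop("category contains values outside low/normal/high")
  strata <- if (is.null(stratum_key)) list() else
    split(categ, records[[stratum_key]])
  strata <- c(strata, list(overall = categ))
  rows <- lapply(names(strata), function(s) {
    counts <- table(strata[[s]])
    data.frame(stratum = s, category = cat_levels,
               count = as.integer(counts),
               percent = round(100 * as.integer(counts) / length(strata[[s]]), 2),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Bland-Altman plot
#'
#' Scatter of the per-eye difference (actual - predicted) against the
#' pairwise mean, with a dotted line at the mean difference and dashed
#' lines at the 95% limits of agreement.
#'
#' @param actual,predicted Numeric vectors, um.
#' @param main Plot title.
#' @param ... Passed to [graphics::plot()].
#' @return The [bland_altman()] summary, invisibly.
#' @export
plot_bland_altman <- function(actual, predicted,
                              main = "Bland-Altman agreement", ...) {
  ba <- bland_altman(actual, predicted)
  avg <- (actual + predicted) / 2
  graphics::plot(avg, actual - predicted,
                 xlab = "Mean of actual and predicted vault (um)",
                 ylab = "Actual - predicted vault (um)",
                 main = main, ...)
  graphics::abline(h = ba$mean_diff, lty = 3)
  graphics::abline(h = ba$loa95, lty = 2)
  invisible(ba)
}
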