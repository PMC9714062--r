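#' Two-sided Fisher exact test on a 2x2 table
#'
#' Exact test of association in a 2x2 contingency table via the
#' hypergeometric distribution with fixed margins. The two-sided p-value
#' follows the probability-mass convention: the sum of point
#' probabilities of all tables (with the same margins) that are no more
#' probable than the observed one, probabilities compared with a
#' relative tolerance of 1e-7 so that ties at machine precision count as
#' equal. Point probabilities come from [stats::dhyper()], which works in
#' log-space and is exact to double precision for totals in the
#' thousands.
#'
#' @param table A 2x2 matrix of nonnegative integer counts, or the four
#'   counts `a, b, c, d` (row-wise: a b / c d). Rows are conventionally
#'   the error groups, columns feature present/absent.
#' @param b,c,d Remaining counts when `table` is given as the scalar `a`.
#' @return Two-sided p-value in [0, 1]. A table with a zero row or
#'   column margin carries no information and returns 1; a zero total is
#'   an error.
#' @export
#' @examples
#' fisher_exact_two_sided(0, 36, 6, 48)   # ciliary body cyst table
fisher_exact_two_sided <- function(table, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(table)) {
    if (!all(dim(table) == c(2L, 2L))) stop("table must be 2x2")
    x <- as.vector(t(table))
  } else {
    x <- c(table, b, c, d)
  }
  if (length(x) != 4L || any(!is.finite(x)) || any(x < 0) ||
      any(x != round(x)))
    stop("counts must be four nonnegative integers")
  a <- x[1]; b <- x[2]; c <- x[3]; d <- x[4]
  n <- a + b + c + d
  if (n == 0) stop("table total is zero")
  m1 <- a + b          # row 1 margin
  k <- a + c           # column 1 margin
  if (m1 == 0 || m1 == n || k == 0 || k == n) return(1)
  support <- max(0, k - (n - m1)):min(k, m1)
  probs <- stats::dhyper(support, m1, n - m1, k)
  p_obs <- stats::dhyper(a, m1, n - m1, k)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  min(max(p, 0), 1)
}

#' Compare UBM features between the large-error groups
#'
#' Restricts a validated cohort to eyes with absolute prediction error
#' greater than 300 um (the overestimated and underestimated groups) and,
#' for each UBM feature present in the data, tabulates presence by group
#' and computes the two-sided Fisher exact p-value.
#'
#' @param records Data.frame carrying an `error_group` column (as from
#'   [assign_error_group()]) and one or more 0/1 feature columns named
#'   after [ubm_features()].
#' @param features Character vector of feature columns to compare;
#'   defaults to whichever of the four standard features are present.
#' @return Data.frame of class `feature_comparison` with one row per
#'   feature: counts and percentages in each group and the p-value.
#' @export
compare_features <- function(records, features = NULL) {
  if (!is.data.frame(records) || !"error_group" %in% names(records))
    stop("records must carry an 'error_group' column")
  if (is.null(features))
    features <- intersect(ubm_features(), names(records))
  if (!length(features)) stop("no UBM feature columns found")
  over <- records[records$error_group == "overestimated", , drop = FALSE]
  under <- records[records$error_group == "underestimated", , drop = FALSE]
  if (nrow(over) == 0L || nrow(under) == 0L)
    stop("both error groups must be nonempty (overestimated n=",
         nrow(over), ", underestimated n=", nrow(under), ")")
  rows <- lapply(features, function(f) {
    a <- sum(over[[f]] == 1)
    cc <- sum(under[[f]] == 1)
    p <- fisher_exact_two_sided(a, nrow(over) - a, cc, nrow(under) - cc)
    data.frame(feature = f,
               n_overestimated = nrow(over),
               count_overestimated = a,
               pct_overestimated = round(100 * a / nrow(over), 2),
               n_underestimated = nrow(under),
               count_underestimated = cc,
               pct_underestimated = round(100 * cc / nrow(under), 2),
               p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("feature_comparison", "data.frame")
  out
}

#' Format a p-value for a report table
#'
#' Three decimals, with values below 0.01 shown as `"<0.01"` — a
#' presentation-layer convention only; the numeric p is never truncated
#' in computation.
#'
#' @param p Numeric p-values.
#' @return Character vector.
#' @export
format_p_value <- function(p) {
  ifelse(p < 0.01, "<0.01", sprintf("%.3f", p))
}
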