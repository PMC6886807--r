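check_pairs <- function(predicted, actual) {
  if (length(predicted) != length(actual)) {
    stop("`predicted` and `actual` must have the same length")
  }
  if (length(actual) == 0) stop("no prediction pairs")
  if (any(!is.finite(actual)) || any(actual < 40 | actual > 400)) {
    stop("actual glucose values must lie in [40, 400] mg/dl")
  }
  if (any(!is.finite(predicted)) || any(predicted <= 0)) {
    stop("predicted values must be finite and positive")
  }
  invisible(NULL)
}

#' Mean absolute relative difference (MARD)
#'
#' The standard CGM accuracy metric: the mean of
#' `|predicted − actual| / actual`, expressed as a percentage. The
#' ground-truth value is the denominator, so a 10 mg/dl error counts for
#' more in the hypoglycemic range than in the hyperglycemic range.
#'
#' @param predicted predicted glucose values in mg/dl (finite, > 0).
#' @param actual observed glucose values in mg/dl, each in \[40, 400\].
#' @return MARD as a percentage.
#' @export
mard <- function(predicted, actual) {
  check_pairs(predicted, actual)
  100 * mean(abs(predicted - actual) / actual)
}

#' MARD restricted to pairs satisfying a criterion
#'
#' Generalizes [mard()] to an arbitrary criterion on the ground truth:
#' only pairs whose actual value satisfies the criterion contribute, and
#' the average is taken over those pairs alone. An empty selection
#' yields `NA` (undefined), never 0.
#'
#' @inheritParams mard
#' @param criterion logical vector selecting pairs, or a function of the
#'   actual values returning one.
#' @return A list with `mard` (percentage or `NA`) and `n` (pairs
#'   selected).
#' @export
mard_where <- function(predicted, actual, criterion) {
  check_pairs(predicted, actual)
  sel <- if (is.function(criterion)) criterion(actual) else criterion
  stopifnot(is.logical(sel), length(sel) == length(actual))
  n <- sum(sel)
  list(
    mard = if (n == 0) NA_real_ else mard(predicted[sel], actual[sel]),
    n = as.integer(n)
  )
}

#' Range-partitioned MARD report
#'
#' Computes overall MARD plus MARD conditioned on the ground truth lying
#' in each glycemic range: hypoglycemic (actual < 70), normal (70–180
#' inclusive) and hyperglycemic (actual > 180). Because most CGM time is
#' spent in the normal range, the overall figure is dominated by it; the
#' range-conditioned values reveal how a model does where alerts
#' actually matter. Empty ranges are reported as `NA` — a model that is
#' never evaluated in a range has no accuracy there, not a perfect one.
#'
#' @inheritParams mard
#' @param thresholds a [glycemic_thresholds()].
#' @return A list of class `mard_report` with `mard_all`, `mard_hypo`,
#'   `mard_norm`, `mard_hyper` and the counts `n_all`, `n_hypo`,
#'   `n_norm`, `n_hyper`. The weighted decomposition
#'   `n_all * mard_all = sum(n_C * mard_C)` holds over the defined
#'   ranges.
#' @export
mard_by_range <- function(predicted, actual,
                          thresholds = glycemic_thresholds()) {
  check_pairs(predicted, actual)
  stopifnot(inherits(thresholds, "glycemic_thresholds"))
  hypo <- mard_where(predicted, actual, actual < thresholds$hypo)
  norm <- mard_where(predicted, actual,
                     actual >= thresholds$hypo & actual <= thresholds$hyper)
  hyper <- mard_where(predicted, actual, actual > thresholds$hyper)
  structure(
    list(
      mard_all = mard(predicted, actual),
      mard_hypo = hypo$mard, mard_norm = norm$mard, mard_hyper = hyper$mard,
      n_all = length(actual),
      n_hypo = hypo$n, n_norm = norm$n, n_hyper = hyper$n
    ),
    class = "mard_report"
  )
}

#' @export
print.mard_report <- function(x, ...) {
  fmt <- function(v, n) {
    if (is.na(v)) sprintf("undefined (n=%d)", n) else sprintf("%.2f%% (n=%d)", v, n)
  }
  cat("MARD report\n")
  cat("  all:  ", fmt(x$mard_all, x$n_all), "\n")
  cat("  <70:  ", fmt(x$mard_hypo, x$n_hypo), "\n")
  cat("  norm: ", fmt(x$mard_norm, x$n_norm), "\n")
  cat("  >180: ", fmt(x$mard_hyper, x$n_hyper), "\n")
  invisible(x)
}

#' Clarke error grid zone of a prediction pair
#'
#' Assigns each (actual, predicted) pair to one of the five Clarke error
#' grid zones, from clinically benign (A) to dangerous (E). Zone A is
#' agreement within 20% of the ground truth, or both values
#' hypoglycemic; zone E is predicting hyperglycemia during actual
#' hypoglycemia or vice versa. The canonical grid inequalities are
#' evaluated with precedence A, E, C, D, else B, so every pair gets
#' exactly one zone and boundary ties resolve toward the earlier zone in
#' that order.
#'
#' @param actual observed glucose values in mg/dl (positive).
#' @param predicted predicted glucose values in mg/dl (positive).
#' @return A factor with levels `A`–`E`, one zone per pair.
#' @export
ega_zone <- function(actual, predicted) {
  stopifnot(length(actual) == length(predicted))
  a <- as.numeric(actual)
  p <- as.numeric(predicted)
  if (any(!is.finite(a)) || any(!is.finite(p)) || any(a <= 0) ||
      any(p <= 0)) {
    stop("EGA inputs must be finite and positive")
  }
  zone <- rep("B", length(a))
  zd <- (a >= 240 & p >= 70 & p <= 180) |
    (a <= 175 / 3 & p >= 70 & p <= 180) |
    (a >= 175 / 3 & a <= 70 & p >= (6 / 5) * a)
  zone[zd] <- "D"
  zc <- (a >= 70 & a <= 290 & p >= a + 110) |
    (a >= 130 & a <= 180 & p <= (7 / 5) * a - 182)
  zone[zc] <- "C"
  ze <- (a <= 70 & p >= 180) | (a >= 180 & p <= 70)
  zone[ze] <- "E"
  za <- (a < 70 & p < 70) | (abs(p - a) <= 0.2 * a)
  zone[za] <- "A"
  factor(zone, levels = c("A", "B", "C", "D", "E"))
}

#' Clarke error grid analysis report
#'
#' Tabulates the percentage of prediction pairs falling into each Clarke
#' zone. Good forecasting maximizes zone A while minimizing B–E; zones C
#' and E are reported but are unreliable for model selection on their
#' own, because a trivial constant predictor can score zero in them.
#'
#' @inheritParams mard
#' @return A list of class `ega_report` with `counts` and `pct` (both
#'   named A–E); percentages sum to 100.
#' @export
ega_report <- function(predicted, actual) {
  check_pairs(predicted, actual)
  z <- ega_zone(actual, predicted)
  counts <- table(z)
  structure(
    list(
      counts = stats::setNames(as.integer(counts), names(counts)),
      pct = stats::setNames(100 * as.numeric(counts) / length(z),
                            names(counts)),
      n = length(z)
    ),
    class = "ega_report"
  )
}

#' @export
print.ega_report <- function(x, ...) {
  cat(sprintf("Clarke EGA over %d pairs\n", x$n))
  for (z in names(x$pct)) {
    cat(sprintf("  zone %s: %6.2f%% (%d)\n", z, x$pct[[z]], x$counts[[z]]))
  }
  invisible(x)
}
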