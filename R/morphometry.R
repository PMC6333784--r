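#' Instrument sensitivity floors for fibril morphometry
#'
#' Default measurement floors, by modality and dimension:
#' * AFM cross-sectional height: instrument electrical noise (0.05 nm) plus
#'   sample roughness (0.1 nm) = 0.15 nm.
#' * AFM length: one pixel of a typical high-resolution scan (0.01 um).
#' * TEM width/length: one pixel at quantification magnification (0.7 nm).
#'
#' @param modality `"AFM"` or `"TEM"`.
#' @param dimension `"length"`, `"height"` or `"width"`.
#' @return The sensitivity floor in the dimension's native units
#'   (um for length, nm otherwise).
#' @export
default_sensitivity <- function(modality, dimension) {
  if (modality == "AFM") {
    if (dimension == "length") 0.01 else 0.15
  } else 0.7
}

#' Per-fibril dimension measurements
#'
#' One set of single-fibril measurements of one dimension from one imaging
#' modality, with the instrument sensitivity floor attached.  Lengths are in
#' micrometres; heights and widths in nanometres.
#'
#' @param values positive per-fibril measurements.
#' @param dimension `"length"`, `"height"` or `"width"`.
#' @param modality `"AFM"` or `"TEM"`.
#' @param sensitivity_error instrument floor in the same units as `values`;
#'   defaults per [default_sensitivity()].
#' @param condition sample label.
#' @param fibril_id optional per-row fibril identifier (TEM widths of
#'   periodic fibrils contribute two rows per fibril: minimum at the
#'   crossover, maximum between crossovers).
#' @return An object of class `fibril_measurements`.
#' @export
fibril_measurements <- function(values,
                                dimension = c("length", "height", "width"),
                                modality = c("AFM", "TEM"),
                                sensitivity_error = NULL,
                                condition = "sample", fibril_id = NULL) {
  dimension <- match.arg(dimension)
  modality <- match.arg(modality)
  if (!is.numeric(values) || !length(values) || anyNA(values) ||
      any(values <= 0))
    ak_validation_error("fibril measurements must be positive numbers")
  if (is.null(sensitivity_error))
    sensitivity_error <- default_sensitivity(modality, dimension)
  if (sensitivity_error < 0)
    ak_validation_error("'sensitivity_error' must be >= 0")
  if (!is.null(fibril_id) && length(fibril_id) != length(values))
    ak_validation_error("'fibril_id' must match 'values' in length")
  structure(list(values = as.numeric(values), dimension = dimension,
                 modality = modality,
                 sensitivity_error = sensitivity_error,
                 condition = as.character(condition),
                 unit = if (dimension == "length") "um" else "nm",
                 fibril_id = fibril_id),
            class = "fibril_measurements")
}

#' @export
print.fibril_measurements <- function(x, ...) {
  cat(sprintf("%s %s of '%s': n = %d, mean = %.3g %s (sensitivity %.3g %s)\n",
              x$modality, x$dimension, x$condition, length(x$values),
              mean(x$values), x$unit, x$sensitivity_error, x$unit))
  invisible(x)
}

#' Summary statistics with the total-error convention
#'
#' Standard summary statistics of a per-fibril measurement set, plus the
#' reporting convention used for imaging data: the total error is the
#' standard error of the mean PLUS the instrument sensitivity floor,
#' `total_error = sem + sensitivity_error`, so that a reported
#' `mean +/- total_error` can never claim a precision below what the
#' instrument resolves.
#'
#' @param mset a [fibril_measurements] object with at least two values.
#' @return A one-row data frame of class `dimension_summary`: `n`, `mean`,
#'   `median`, `q1`, `q3`, `sd`, `sem`, `sensitivity_error`, `total_error`,
#'   plus `condition`, `dimension`, `modality`, `unit`.
#' @export
summarize_dimensions <- function(mset) {
  stopifnot(inherits(mset, "fibril_measurements"))
  v <- mset$values
  n <- length(v)
  if (n < 2L)
    ak_validation_error("at least two measurements are required for statistics")
  s <- stats::sd(v)
  sem <- s / sqrt(n)
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
  out <- data.frame(condition = mset$condition, dimension = mset$dimension,
                    modality = mset$modality, unit = mset$unit,
                    n = n, mean = mean(v), median = q[2L], q1 = q[1L],
                    q3 = q[3L], sd = s, sem = sem,
                    sensitivity_error = mset$sensitivity_error,
                    total_error = sem + mset$sensitivity_error,
                    stringsAsFactors = FALSE)
  class(out) <- c("dimension_summary", "data.frame")
  out
}

#' Sensitivity-aware comparison of two fibril populations
#'
#' Welch two-sample t-test of the difference in mean dimension between two
#' conditions, tested against a null offset equal to the instrument
#' sensitivity floor: the observed difference is shifted towards zero by
#' `sensitivity_error` before testing, so a difference no larger than what
#' the instrument can resolve is never declared significant.  With a zero
#' sensitivity floor this reduces exactly to the standard (two-sided) Welch
#' test.
#'
#' @param a,b [fibril_measurements] of the same dimension and modality.
#' @param alpha significance level for the `significant` flag.
#' @return A list: `t` (statistic), `df`, `p`, `significant`, `stars`
#'   (`"***"` p < 0.001, `"**"` p < 0.01, `"*"` p < 0.05, `"ns"`),
#'   `mean_difference`, `shift` (sensitivity offset applied).
#' @export
compare_conditions <- function(a, b, alpha = 0.05) {
  stopifnot(inherits(a, "fibril_measurements"),
            inherits(b, "fibril_measurements"))
  if (a$dimension != b$dimension || a$modality != b$modality)
    ak_validation_error("measurement sets differ in dimension or modality")
  if (length(a$values) < 2L || length(b$values) < 2L)
    ak_validation_error("both sets need at least two measurements")
  s <- max(a$sensitivity_error, b$sensitivity_error)
  delta <- mean(a$values) - mean(b$values)
  shift <- sign(delta) * min(s, abs(delta))
  tt <- stats::t.test(a$values, b$values, mu = shift, var.equal = FALSE)
  p <- tt$p.value
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = p,
       significant = p < alpha,
       stars = if (p < 0.001) "***" else if (p < 0.01) "**"
               else if (p < alpha) "*" else "ns",
       mean_difference = delta, shift = shift)
}

#' Ratio of mean fibril lengths with propagated error
#'
#' Mean treated length over mean control length, with first-order error
#' propagation from the two total errors:
#' `err = ratio * sqrt((e_t/m_t)^2 + (e_c/m_c)^2)`.
#'
#' @param treated,control [fibril_measurements] of dimension `"length"`.
#' @return A list with `ratio`, `error`, and the two condition summaries.
#' @export
length_ratio <- function(treated, control) {
  stopifnot(inherits(treated, "fibril_measurements"),
            inherits(control, "fibril_measurements"))
  if (treated$dimension != "length" || control$dimension != "length")
    ak_validation_error("length_ratio() requires length measurements")
  st <- summarize_dimensions(treated)
  sc <- summarize_dimensions(control)
  r <- st$mean / sc$mean
  err <- r * sqrt((st$total_error / st$mean)^2 + (sc$total_error / sc$mean)^2)
  list(ratio = r, error = err, treated = st, control = sc)
}

#' Consistency of an observed length ratio with the kinetic prediction
#'
#' Checks whether an observed fibril-length ratio agrees with the
#' \eqn{\sqrt{k_+/k_2}} scaling prediction for given fold-changes of the two
#' rate constants, within a stated tolerance.
#'
#' @param observed_ratio observed mean-length ratio (treated / control).
#' @param factor_k2,factor_kplus fold-changes of the rate constants.
#' @param tolerance allowed absolute deviation between observed and
#'   predicted ratio.
#' @return A list: `consistent` (logical), `predicted`, `observed`,
#'   `deviation`, `tolerance`.
#' @examples
#' scaling_consistency(0.348, factor_k2 = 5, tolerance = 0.15)
#' @export
scaling_consistency <- function(observed_ratio, factor_k2, factor_kplus = 1,
                                tolerance = 0.15) {
  if (!is.numeric(observed_ratio) || observed_ratio <= 0)
    ak_validation_error("'observed_ratio' must be positive")
  if (tolerance < 0) ak_validation_error("'tolerance' must be >= 0")
  pred <- predicted_length_scale(factor_k2, factor_kplus)
  dev <- abs(observed_ratio - pred)
  list(consistent = dev <= tolerance, predicted = pred,
       observed = observed_ratio, deviation = dev, tolerance = tolerance)
}
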