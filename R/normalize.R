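#' Normalize a raw fluorescence trace to the 0--1 aggregate-mass scale
#'
#' Thioflavin-T fluorescence is proportional to fibril mass up to an affine
#' transformation per well.  Each trace is therefore normalized
#' independently: the baseline is the mean of the first `baseline_window`
#' fraction of points, the plateau the mean of the last `plateau_window`
#' fraction, and the signal is mapped through
#' `(value - baseline) / (plateau - baseline)`.
#'
#' The map inverts any affine transform `a * x + b` (a > 0) of an
#' already-normalized trace, and is idempotent on traces with flat 0/1 ends.
#'
#' @param raw a [kinetic_trace] (raw or normalized).
#' @param baseline_window fraction of early points averaged for the baseline
#'   (in (0, 0.5)).
#' @param plateau_window fraction of late points averaged for the plateau.
#' @return A normalized [kinetic_trace].
#' @export
normalize_trace <- function(raw, baseline_window = 0.1, plateau_window = 0.1) {
  stopifnot(inherits(raw, "kinetic_trace"))
  if (baseline_window <= 0 || baseline_window >= 0.5 ||
      plateau_window <= 0 || plateau_window >= 0.5)
    ak_validation_error("normalization windows must lie in (0, 0.5)")
  n <- length(raw$values)
  nb <- max(1L, floor(baseline_window * n))
  np <- max(1L, floor(plateau_window * n))
  baseline <- mean(raw$values[seq_len(nb)])
  plateau <- mean(raw$values[seq.int(n - np + 1L, n)])
  if (plateau <= baseline)
    ak_validation_error(sprintf(
      "no aggregation signal in trace '%s': plateau (%.4g) <= baseline (%.4g)",
      raw$label, plateau, baseline))
  out <- raw
  out$values <- (raw$values - baseline) / (plateau - baseline)
  out$normalized <- TRUE
  out
}
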