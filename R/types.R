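#' Microscopic rate constants of the aggregation network
#'
#' Bundles the rate constants and reaction orders of the three microscopic
#' processes that build amyloid fibrils from monomer: primary nucleation
#' (`k_n`), elongation at fibril ends (`k_plus`) and monomer-dependent
#' secondary nucleation on fibril surfaces (`k_2`).  Units are micromolar and
#' hours throughout: `k_n` in uM^(1-n_c) h^-1, `k_plus` in uM^-1 h^-1 and
#' `k_2` in uM^(-n_2) h^-1.
#'
#' The reaction orders default to `n_c = 2`, `n_2 = 2`, the standard values
#' for Abeta42 in the secondary-nucleation framework.
#'
#' @param k_n primary nucleation rate constant (>= 0).
#' @param k_plus elongation rate constant (>= 0).
#' @param k_2 secondary nucleation rate constant (>= 0).
#' @param n_c primary nucleation reaction order (>= 1).
#' @param n_2 secondary nucleation reaction order (>= 0).
#' @return An object of class `rate_constants`.
#' @examples
#' rate_constants(k_n = 2e-7, k_plus = 1e3, k_2 = 2e-3)
#' @export
rate_constants <- function(k_n, k_plus, k_2, n_c = 2, n_2 = 2) {
  for (nm in c("k_n", "k_plus", "k_2", "n_c", "n_2")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      ak_validation_error(sprintf("'%s' must be a single finite number", nm))
  }
  if (k_n < 0 || k_plus < 0 || k_2 < 0)
    ak_validation_error("rate constants must be non-negative")
  if (n_c < 1) ak_validation_error("'n_c' must be >= 1")
  if (n_2 < 0) ak_validation_error("'n_2' must be >= 0")
  structure(list(k_n = k_n, k_plus = k_plus, k_2 = k_2,
                 n_c = n_c, n_2 = n_2),
            class = "rate_constants")
}

#' @export
print.rate_constants <- function(x, ...) {
  cat("Aggregation rate constants (uM, h):\n")
  cat(sprintf("  k_n    = %.4g uM^(1-n_c) h^-1   (n_c = %g)\n", x$k_n, x$n_c))
  cat(sprintf("  k_plus = %.4g uM^-1 h^-1\n", x$k_plus))
  cat(sprintf("  k_2    = %.4g uM^(-n_2) h^-1    (n_2 = %g)\n", x$k_2, x$n_2))
  cat(sprintf("  products: k+k2 = %.4g, k+kn = %.4g\n",
              x$k_plus * x$k_2, x$k_plus * x$k_n))
  invisible(x)
}

#' Initial reaction conditions of an aggregation assay
#'
#' Defines the initial state of a (possibly seeded) aggregation reaction.
#' `m_total` is the total monomer-equivalent peptide concentration; a fraction
#' `seed_fraction` of it is supplied as pre-formed fibrils ("seeds", stated as
#' monomer equivalents), so the initial free monomer is
#' `m0 = (1 - seed_fraction) * m_total`, the initial fibril mass is
#' `M0 = seed_fraction * m_total` and the initial fibril number concentration
#' is `P0 = M0 / seed_length`.
#'
#' `seed_length` (mean seed size in monomer units) is a convention: only the
#' product `k_plus * P0` is observable at early times, so analyses report
#' fold-changes relative to a shared control, which are invariant to it.
#'
#' @param m_total total peptide concentration (uM, > 0).
#' @param seed_fraction pre-formed fibril mass fraction (in `[0, 1)`).
#' @param seed_length mean seed length in monomer units (> 0; default 500).
#' @return An object of class `reaction_conditions` with derived fields
#'   `m0`, `M0` and `P0`.
#' @examples
#' reaction_conditions(m_total = 2, seed_fraction = 0.05)
#' @export
reaction_conditions <- function(m_total, seed_fraction = 0, seed_length = 500) {
  if (!is.numeric(m_total) || length(m_total) != 1L || !is.finite(m_total) ||
      m_total <= 0)
    ak_validation_error("'m_total' must be a single positive number (uM)")
  if (!is.numeric(seed_fraction) || length(seed_fraction) != 1L ||
      !is.finite(seed_fraction) || seed_fraction < 0 || seed_fraction >= 1)
    ak_validation_error("'seed_fraction' must lie in [0, 1)")
  if (!is.numeric(seed_length) || length(seed_length) != 1L ||
      !is.finite(seed_length) || seed_length <= 0)
    ak_validation_error("'seed_length' must be a positive number")
  M0 <- seed_fraction * m_total
  structure(list(m_total = m_total, seed_fraction = seed_fraction,
                 seed_length = seed_length,
                 m0 = (1 - seed_fraction) * m_total,
                 M0 = M0,
                 P0 = if (seed_fraction > 0) M0 / seed_length else 0),
            class = "reaction_conditions")
}

#' @export
print.reaction_conditions <- function(x, ...) {
  cat(sprintf(
    "Reaction conditions: m_total = %g uM, seed fraction = %g%% (m0 = %g, M0 = %g, P0 = %.3g uM)\n",
    x$m_total, 100 * x$seed_fraction, x$m0, x$M0, x$P0))
  invisible(x)
}

#' Kinetic trace container
#'
#' A single well's time series of aggregate-mass signal.  `values` are either
#' raw fluorescence (arbitrary units, `normalized = FALSE`) or a dimensionless
#' normalized signal on the 0--1 scale (`normalized = TRUE`).  Condition
#' metadata (total monomer, seed fraction, modulator dose) travels with the
#' trace so that multi-condition fits can be assembled from a flat list.
#'
#' @param times time grid in hours; strictly increasing, length >= 8.
#' @param values signal at each time point.
#' @param label condition identifier.
#' @param normalized logical; is the trace on the normalized 0--1 scale?
#' @param replicate replicate identifier within the condition.
#' @param m_total total peptide concentration of the well (uM).
#' @param seed_fraction seed mass fraction of the well.
#' @param modulator_ratio modulator-to-peptide molar ratio (0 for controls).
#' @param seed_length mean seed length convention (monomer units).
#' @return An object of class `kinetic_trace`.
#' @export
kinetic_trace <- function(times, values, label = "trace", normalized = FALSE,
                          replicate = 1L, m_total = NA_real_,
                          seed_fraction = NA_real_, modulator_ratio = NA_real_,
                          seed_length = 500) {
  if (length(times) != length(values))
    ak_validation_error("'times' and 'values' must have equal length")
  if (length(times) < 8L)
    ak_validation_error("a kinetic trace needs at least 8 time points")
  if (anyNA(times) || is.unsorted(times, strictly = TRUE))
    ak_validation_error(sprintf(
      "times of trace '%s' must be strictly increasing", label))
  if (isTRUE(normalized) &&
      (min(values) < -0.1 - 1e-9 || max(values) > 1.1 + 1e-9))
    ak_validation_error(sprintf(
      "normalized trace '%s' has values outside [-0.1, 1.1]", label))
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 label = as.character(label), normalized = isTRUE(normalized),
                 replicate = replicate, m_total = m_total,
                 seed_fraction = seed_fraction,
                 modulator_ratio = modulator_ratio, seed_length = seed_length),
            class = "kinetic_trace")
}

#' @export
print.kinetic_trace <- function(x, ...) {
  cat(sprintf("Kinetic trace '%s' (replicate %s): %d points, t = %.3g..%.3g h, %s\n",
              x$label, as.character(x$replicate), length(x$times),
              min(x$times), max(x$times),
              if (x$normalized) "normalized" else "raw a.u."))
  invisible(x)
}
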