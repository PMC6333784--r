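#' Reference rate constants for Abeta42-like synthetic kinetics
#'
#' The base rate constants used by the synthetic generator and as the centre
#' of the fitting search box.  They are calibrated (in uM, h units, with the
#' 500-monomer seed-length convention) so that a 2 uM reaction reproduces the
#' benchmark study conditions: an unseeded half-time of order 1 h
#' (about 2.1 h), a 25%-seeded half-time of 0.28 h, and a reduction to
#' about 0.19 h when k_2 is increased five-fold at 25% seeds.
#'
#' @return A [rate_constants] object.
#' @export
abeta42_rates <- function() {
  rate_constants(k_n = 1.8e-7, k_plus = 975, k_2 = 1.68e-3, n_c = 2, n_2 = 2)
}

#' Specification for the synthetic trace generator
#'
#' @param rates base [rate_constants] shared by all conditions.
#' @param conditions a data frame with one row per condition: columns
#'   `label`, `m_total`, `seed_fraction`, `modulator_ratio` and optionally
#'   `seed_length` (default 500).
#' @param perturbation a [perturbation_hypothesis] whose `factors` name every
#'   non-control condition (fold-changes planted on the targeted step).
#' @param noise_sd additive Gaussian noise, in normalized mass-fraction
#'   units (default 0.02, typical thioflavin-T replicate scatter).
#' @param replicates replicate wells per condition (>= 1).
#' @param t_max trace duration in hours.
#' @param n_points time points per trace (>= 8).
#' @param seed integer seed; generation is fully deterministic.
#' @param drift_slope optional linear baseline drift (signal units per hour)
#'   for robustness experiments; 0 by default.
#' @return A list of class `generator_spec`.
#' @export
generator_spec <- function(rates, conditions, perturbation,
                           noise_sd = 0.02, replicates = 3, t_max = 5,
                           n_points = 150, seed = 1, drift_slope = 0) {
  stopifnot(inherits(rates, "rate_constants"),
            inherits(perturbation, "perturbation_hypothesis"),
            is.data.frame(conditions))
  need <- c("label", "m_total", "seed_fraction", "modulator_ratio")
  if (!all(need %in% names(conditions)))
    ak_validation_error(paste("'conditions' needs columns:",
                              paste(need, collapse = ", ")))
  if (is.null(conditions$seed_length)) conditions$seed_length <- 500
  if (anyDuplicated(conditions$label))
    ak_validation_error("condition labels must be unique")
  if (noise_sd < 0) ak_validation_error("'noise_sd' must be >= 0")
  if (replicates < 1) ak_validation_error("'replicates' must be >= 1")
  if (n_points < 8) ak_validation_error("'n_points' must be >= 8")
  perturbed <- conditions$label[conditions$modulator_ratio > 0]
  f <- perturbation$factors
  if (perturbation$target != "none" || length(perturbed)) {
    if (!setequal(names(f), perturbed))
      ak_validation_error(
        "perturbation factors must name exactly the non-control conditions")
  }
  structure(list(rates = rates, conditions = conditions,
                 perturbation = perturbation, noise_sd = noise_sd,
                 replicates = as.integer(replicates), t_max = t_max,
                 n_points = as.integer(n_points), seed = as.integer(seed),
                 drift_slope = drift_slope),
            class = "generator_spec")
}

#' Generate synthetic thioflavin-T-style traces with planted ground truth
#'
#' Emulates a plate-reader aggregation assay: for every condition the
#' normalized aggregate-mass signal is computed from the closed-form model
#' under the planted per-condition perturbation, and i.i.d. Gaussian noise
#' (plus an optional linear drift) is added per replicate.  The returned
#' ground-truth record contains everything needed to regenerate every
#' noiseless curve bit-identically.
#'
#' @param spec a [generator_spec].
#' @return A list with `traces` (list of normalized [kinetic_trace]) and
#'   `truth` (rates, planted factors, noise level, seed, RNG identifier,
#'   conditions table).
#' @export
generate_tht_traces <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  set.seed(spec$seed)
  tg <- seq(0, spec$t_max, length.out = spec$n_points)
  traces <- list()
  for (i in seq_len(nrow(spec$conditions))) {
    row <- spec$conditions[i, ]
    cond <- reaction_conditions(row$m_total, row$seed_fraction,
                                row$seed_length)
    f <- 1
    if (row$modulator_ratio > 0)
      f <- unname(spec$perturbation$factors[[row$label]])
    r <- .apply_factor(spec$rates, spec$perturbation$target, f)
    q <- .model_signal(tg, r, cond)
    for (j in seq_len(spec$replicates)) {
      noisy <- q + stats::rnorm(length(tg), 0, spec$noise_sd) +
        spec$drift_slope * tg
      traces[[length(traces) + 1L]] <-
        kinetic_trace(tg, noisy, label = row$label, normalized = TRUE,
                      replicate = j, m_total = row$m_total,
                      seed_fraction = row$seed_fraction,
                      modulator_ratio = row$modulator_ratio,
                      seed_length = row$seed_length)
    }
  }
  list(traces = traces,
       truth = list(rates = spec$rates,
                    target = spec$perturbation$target,
                    factors = spec$perturbation$factors,
                    noise_sd = spec$noise_sd, replicates = spec$replicates,
                    t_max = spec$t_max, n_points = spec$n_points,
                    seed = spec$seed, rng = RNGkind()[1L],
                    drift_slope = spec$drift_slope,
                    conditions = spec$conditions))
}

#' Lognormal per-fibril dimension sample
#'
#' Fibril dimensions are unimodal and right-skewed; a lognormal sample (mean
#' `exp(log_mean + log_sd^2/2)`) emulates them.  Deterministic per seed.
#'
#' @param n number of fibrils (>= 1).
#' @param log_mean mean of log dimension (log-um for lengths, log-nm
#'   otherwise).
#' @param log_sd standard deviation of log dimension (>= 0).
#' @param dimension,modality,condition,sensitivity_error passed to
#'   [fibril_measurements()].
#' @param seed integer seed.
#' @return A [fibril_measurements] object.
#' @export
generate_fibril_dimensions <- function(n, log_mean, log_sd,
                                       dimension = "length",
                                       modality = "AFM", seed = 1,
                                       condition = "sample",
                                       sensitivity_error = NULL) {
  if (n < 1) ak_validation_error("'n' must be >= 1")
  if (log_sd < 0) ak_validation_error("'log_sd' must be >= 0")
  set.seed(as.integer(seed))
  fibril_measurements(stats::rlnorm(n, log_mean, log_sd),
                      dimension = dimension, modality = modality,
                      condition = condition,
                      sensitivity_error = sensitivity_error)
}

#' Morphometry generator presets anchored to the benchmark means
#'
#' Preset lognormal parameters whose population means equal the benchmark
#' dimension means: AFM lengths 1.81 um (control) and 0.63 um (treated, n =
#' 100 each), AFM heights 4.2 nm (n = 387) and 6.3 nm (n = 174), TEM widths
#' 12 nm and 15 nm (n = 200 each).  Log-sds are generator choices (0.55 for
#' the broad length distributions, 0.18 for cross-sections).
#'
#' @param name one of `"length_control"`, `"length_treated"`,
#'   `"height_control"`, `"height_treated"`, `"width_control"`,
#'   `"width_treated"`.
#' @return A list with `mean`, `log_mean`, `log_sd`, `dimension`,
#'   `modality`, `condition` and `n` (the benchmark sample size).
#' @export
fibril_dimension_preset <- function(name) {
  presets <- list(
    length_control = list(mean = 1.81, log_sd = 0.55, dimension = "length",
                          modality = "AFM", condition = "control", n = 100L),
    length_treated = list(mean = 0.63, log_sd = 0.55, dimension = "length",
                          modality = "AFM", condition = "treated", n = 100L),
    height_control = list(mean = 4.2, log_sd = 0.18, dimension = "height",
                          modality = "AFM", condition = "control", n = 387L),
    height_treated = list(mean = 6.3, log_sd = 0.18, dimension = "height",
                          modality = "AFM", condition = "treated", n = 174L),
    width_control = list(mean = 12, log_sd = 0.2, dimension = "width",
                         modality = "TEM", condition = "control", n = 200L),
    width_treated = list(mean = 15, log_sd = 0.2, dimension = "width",
                         modality = "TEM", condition = "treated", n = 200L))
  if (!name %in% names(presets))
    ak_validation_error(paste("unknown preset; choose one of:",
                              paste(names(presets), collapse = ", ")))
  p <- presets[[name]]
  p$log_mean <- log(p$mean) - p$log_sd^2 / 2
  p
}

.fixture_conditions <- function(seed_fraction) {
  data.frame(
    label = paste0(c("ctrl", "tro_10to1", "tro_5to1", "tro_1to1"),
                   if (seed_fraction > 0)
                     paste0("_s", round(100 * seed_fraction)) else ""),
    m_total = 2,
    seed_fraction = seed_fraction,
    modulator_ratio = c(0, 0.1, 0.2, 1),
    seed_length = 500,
    stringsAsFactors = FALSE)
}

#' Canonical synthetic benchmark bundle
#'
#' One fixed, fully deterministic bundle emulating the benchmark experiment
#' set: unseeded, 5%-seeded and 25%-seeded dose series of 2 uM peptide with
#' modulator at 10:1, 5:1 and 1:1 peptide-to-modulator ratios, plus
#' morphometry tables.  Planted fold-changes on the secondary pathway are
#' 2, 4.5 and 5 (culminating in the five-fold enhancement at the equimolar
#' ratio); the base rates are [abeta42_rates()], calibrated so the
#' 25%-seeded control and equimolar half-times emulate 0.28 h and 0.19 h.
#' Unseeded conditions plant the factor on the product k+k2
#' (`secondary_product`), seeded conditions on k_2 alone (`k2_only`).
#'
#' @param seed master seed; group sub-seeds are derived as seed, seed+1, ...
#' @param noise_sd Gaussian noise in normalized units.
#' @param replicates wells per condition.
#' @return A list of class `paper_fixture`: `traces` (named list of trace
#'   lists `unseeded`, `seeded_5`, `seeded_25`), `morphometry` (named list of
#'   [fibril_measurements]), and `truth` (per-group ground-truth records plus
#'   the planted morphometry presets).
#' @export
make_paper_fixture <- function(seed = 20260921, noise_sd = 0.02,
                               replicates = 3) {
  factors <- c(2, 4.5, 5)
  groups <- list(
    unseeded = list(s = 0, t_max = 5, n_points = 151,
                    target = "secondary_product"),
    seeded_5 = list(s = 0.05, t_max = 1.5, n_points = 121,
                    target = "k2_only"),
    seeded_25 = list(s = 0.25, t_max = 1.2, n_points = 121,
                     target = "k2_only"))
  traces <- list(); truth <- list()
  for (g in seq_along(groups)) {
    gr <- groups[[g]]
    conds <- .fixture_conditions(gr$s)
    f <- factors
    names(f) <- conds$label[conds$modulator_ratio > 0]
    spec <- generator_spec(abeta42_rates(), conds,
                           perturbation_hypothesis(gr$target, f),
                           noise_sd = noise_sd, replicates = replicates,
                           t_max = gr$t_max, n_points = gr$n_points,
                           seed = seed + g - 1L)
    out <- generate_tht_traces(spec)
    traces[[names(groups)[g]]] <- out$traces
    truth[[names(groups)[g]]] <- out$truth
  }
  morph <- list(); mseed <- seed + 100L
  for (nm in c("length_control", "length_treated", "height_control",
               "height_treated", "width_control", "width_treated")) {
    p <- fibril_dimension_preset(nm)
    morph[[nm]] <- generate_fibril_dimensions(
      p$n, p$log_mean, p$log_sd, dimension = p$dimension,
      modality = p$modality, seed = mseed, condition = p$condition)
    mseed <- mseed + 1L
  }
  truth$morphometry <- lapply(c("length_control", "length_treated",
                                "height_control", "height_treated",
                                "width_control", "width_treated"),
                              fibril_dimension_preset)
  truth$seed <- seed
  structure(list(traces = traces, morphometry = morph, truth = truth),
            class = "paper_fixture")
}
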