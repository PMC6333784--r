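#' Mechanistic perturbation hypothesis
#'
#' Declares which microscopic step a modulator is assumed to perturb.  In a
#' global fit every non-control condition receives one multiplicative
#' fold-change ("factor") applied to the targeted step; the control factor is
#' fixed at 1.
#'
#' Targets:
#' * `"none"` -- no per-condition factors (null model).
#' * `"primary"` -- scales the primary-pathway product k+kn (via k_n).
#' * `"secondary_product"` -- scales the secondary-pathway product k+k2
#'   (via k_2; for unseeded data only the product is observable, so this
#'   split is a convention).
#' * `"k2_only"` -- scales the secondary nucleation rate constant alone.
#' * `"kplus_only"` -- scales the elongation rate constant alone (this also
#'   changes both products and the seed elongation rate).
#'
#' @param target character; one of the five targets above.
#' @param factors optional named numeric vector of planted fold-changes
#'   (used by the synthetic generator; fitted otherwise).  Must be positive
#'   and finite.
#' @return An object of class `perturbation_hypothesis`.
#' @export
perturbation_hypothesis <- function(target = c("none", "primary",
                                               "secondary_product",
                                               "k2_only", "kplus_only"),
                                    factors = NULL) {
  target <- match.arg(target)
  if (!is.null(factors)) {
    if (!is.numeric(factors) || anyNA(factors) || any(factors <= 0) ||
        any(!is.finite(factors)))
      ak_validation_error("'factors' must be positive finite fold-changes")
    if (is.null(names(factors)) || any(names(factors) == ""))
      ak_validation_error("'factors' must be named by condition label")
  }
  structure(list(target = target, factors = factors),
            class = "perturbation_hypothesis")
}

# Apply a fold-change to the step targeted by a hypothesis.
.apply_factor <- function(rates, target, f) {
  switch(target,
         none = rates,
         primary = rate_constants(rates$k_n * f, rates$k_plus, rates$k_2,
                                  rates$n_c, rates$n_2),
         secondary_product = ,
         k2_only = rate_constants(rates$k_n, rates$k_plus, rates$k_2 * f,
                                  rates$n_c, rates$n_2),
         kplus_only = rate_constants(rates$k_n, rates$k_plus * f, rates$k_2,
                                     rates$n_c, rates$n_2))
}

# Fold-change of the apparent secondary-pathway product k+k2 implied by a
# fitted factor (the dose-response quantity plotted against modulator dose).
.apparent_rate_ratio <- function(target, f) {
  switch(target,
         none = rep(1, length(f)),
         primary = rep(1, length(f)),
         secondary_product = f,
         k2_only = f,
         kplus_only = f)
}

#' Configuration for global kinetic fitting
#'
#' @param seed integer seed; the whole fit (basin-hopping included) is
#'   deterministic given the seed.
#' @param n_hops maximum number of basin-hopping iterations (random restarts
#'   around the incumbent followed by a local quasi-Newton polish).
#' @param stall_hops stop early after this many consecutive hops without
#'   improvement.
#' @param hop_sd standard deviation of the log10-space hop proposal.
#' @param centers a [rate_constants] object at the centre of the log-space
#'   search box (literature-scale Abeta42 values by default).
#' @param bounds_decades half-width of the base-rate search box in decades
#'   (default 3, i.e. a six-decade span).
#' @param factor_bounds allowed range for per-condition fold-changes.
#' @param quad_nodes conversion nodes for the seeded-condition solver.
#' @param verbose log each basin hop via `message()`.
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(seed = 0, n_hops = 50, stall_hops = 8, hop_sd = 0.4,
                       centers = abeta42_rates(), bounds_decades = 3,
                       factor_bounds = c(1e-2, 1e2), quad_nodes = 1000,
                       verbose = FALSE) {
  stopifnot(inherits(centers, "rate_constants"), n_hops >= 0,
            length(factor_bounds) == 2L, factor_bounds[1L] > 0,
            factor_bounds[2L] > factor_bounds[1L])
  structure(list(seed = as.integer(seed), n_hops = n_hops,
                 stall_hops = stall_hops, hop_sd = hop_sd, centers = centers,
                 bounds_decades = bounds_decades,
                 factor_bounds = factor_bounds, quad_nodes = quad_nodes,
                 verbose = isTRUE(verbose)),
            class = "fit_config")
}

# Group traces by condition label and extract per-condition metadata.
.condition_table <- function(traces) {
  if (!length(traces)) ak_validation_error("no traces supplied")
  for (tr in traces) {
    if (!inherits(tr, "kinetic_trace"))
      ak_validation_error("all elements must be kinetic_trace objects")
    if (!isTRUE(tr$normalized))
      ak_validation_error(sprintf(
        "trace '%s' is not normalized; apply normalize_trace() first", tr$label))
    if (anyNA(c(tr$m_total, tr$seed_fraction, tr$modulator_ratio)))
      ak_validation_error(sprintf(
        "trace '%s' lacks condition metadata (m_total, seed_fraction, modulator_ratio)",
        tr$label))
  }
  labs <- vapply(traces, `[[`, "", "label")
  meta <- do.call(rbind, lapply(split(seq_along(traces), labs), function(ix) {
    tr <- traces[[ix[1L]]]
    for (j in ix[-1L]) {
      o <- traces[[j]]
      if (o$m_total != tr$m_total || o$seed_fraction != tr$seed_fraction)
        ak_validation_error(sprintf(
          "replicates of condition '%s' disagree on m_total/seed_fraction",
          tr$label))
    }
    data.frame(label = tr$label, m_total = tr$m_total,
               seed_fraction = tr$seed_fraction,
               modulator_ratio = tr$modulator_ratio,
               seed_length = tr$seed_length, stringsAsFactors = FALSE)
  }))
  meta <- meta[order(meta$modulator_ratio, meta$label), , drop = FALSE]
  rownames(meta) <- NULL
  meta
}

# Build the residual-sum-of-squares objective over all traces.
.make_objective <- function(traces, meta, target, config) {
  labs <- vapply(traces, `[[`, "", "label")
  cond_of <- lapply(seq_len(nrow(meta)), function(i)
    reaction_conditions(meta$m_total[i], meta$seed_fraction[i],
                        meta$seed_length[i]))
  obs <- lapply(seq_len(nrow(meta)), function(i) {
    ix <- which(labs == meta$label[i])
    list(times = traces[[ix[1L]]]$times,
         values = vapply(ix, function(j) traces[[j]]$values,
                         numeric(length(traces[[ix[1L]]]$times))))
  })
  # replicates of a condition must share the time grid for a joint model eval
  for (i in seq_len(nrow(meta))) {
    ix <- which(labs == meta$label[i])
    for (j in ix) if (!isTRUE(all.equal(traces[[j]]$times, obs[[i]]$times)))
      ak_validation_error(sprintf(
        "replicates of condition '%s' have different time grids", meta$label[i]))
  }
  perturbed <- which(meta$modulator_ratio > 0)
  fit_kp <- any(meta$seed_fraction > 0)   # k+ only observable via seeds
  cen <- config$centers

  list(
    n_base = 2L + fit_kp,
    n_factors = if (target == "none") 0L else length(perturbed),
    perturbed = perturbed,
    fit_kp = fit_kp,
    n_obs = sum(vapply(obs, function(o) length(o$values), 0)),
    lower = c(log10(cen$k_n) - config$bounds_decades,
              log10(cen$k_2) - config$bounds_decades,
              if (fit_kp) log10(cen$k_plus) - config$bounds_decades,
              rep(log10(config$factor_bounds[1L]),
                  if (target == "none") 0L else length(perturbed))),
    upper = c(log10(cen$k_n) + config$bounds_decades,
              log10(cen$k_2) + config$bounds_decades,
              if (fit_kp) log10(cen$k_plus) + config$bounds_decades,
              rep(log10(config$factor_bounds[2L]),
                  if (target == "none") 0L else length(perturbed))),
    start = c(log10(cen$k_n), log10(cen$k_2),
              if (fit_kp) log10(cen$k_plus),
              rep(0, if (target == "none") 0L else length(perturbed))),
    rss = function(par) {
      kn <- 10^par[1L]; k2 <- 10^par[2L]
      kp <- if (fit_kp) 10^par[3L] else cen$k_plus
      base <- rate_constants(kn, kp, k2, cen$n_c, cen$n_2)
      lf <- if (target == "none" || !length(perturbed)) numeric(0)
            else par[seq.int(2L + fit_kp + 1L, length(par))]
      total <- 0
      for (i in seq_len(nrow(meta))) {
        f <- 1
        if (target != "none") {
          k <- match(i, perturbed)
          if (!is.na(k)) f <- 10^lf[k]
        }
        r <- .apply_factor(base, target, f)
        q <- .model_signal(obs[[i]]$times, r, cond_of[[i]],
                           n_nodes = config$quad_nodes)
        if (anyNA(q) || any(!is.finite(q))) return(1e10)
        total <- total + sum((obs[[i]]$values - q)^2)
      }
      total
    })
}

.local_fit <- function(fn, start, lower, upper) {
  res <- stats::nlminb(start, fn, lower = lower, upper = upper,
                       control = list(iter.max = 300, eval.max = 600))
  list(par = res$par, value = res$objective,
       converged = res$convergence == 0)
}

#' Global fit of multi-condition aggregation traces
#'
#' Fits the closed-form aggregation model to all normalized traces of all
#' conditions simultaneously by plain least squares: the base rate constants
#' are shared across conditions and each non-control condition receives one
#' fold-change on the step named by `hypothesis`.  The search runs in log10
#' space inside a bounded box and uses basin-hopping (random restarts around
#' the incumbent, each polished by a bounded quasi-Newton local
#' optimization), seeded and fully deterministic.
#'
#' The base parameters are `log10 k_n` and `log10 k_2`; `log10 k_plus` is
#' additionally freed when any condition is seeded (unseeded data constrain
#' only the products k+k2 and k+kn, so k+ is held at its `centers` value
#' there).
#'
#' Identifiability is probed after convergence by a symmetric two-point
#' curvature scan of each factor (relative rss change when the factor is
#' multiplied/divided by sqrt(2)); factors whose curvature score falls below
#' 0.01 are flagged in `warnings` as effectively unidentifiable (for example
#' a k2-only factor under heavily seeded, elongation-dominated conditions).
#'
#' @param traces list of normalized [kinetic_trace] objects with condition
#'   metadata; at least one control (modulator_ratio 0) required.
#' @param hypothesis a [perturbation_hypothesis].
#' @param config a [fit_config].
#' @return An object of class `amylokin_fit` with elements `base_rates`,
#'   `fitted_factors` (named, controls at 1), `apparent_rate_ratio`,
#'   `factor_sensitivity`, `rss`, `aic`, `n_obs`, `n_params`, `converged`,
#'   `seed`, `hypothesis`, `conditions` and `warnings`.
#' @export
fit_global <- function(traces, hypothesis, config = fit_config()) {
  stopifnot(inherits(hypothesis, "perturbation_hypothesis"),
            inherits(config, "fit_config"))
  meta <- .condition_table(traces)
  if (!any(meta$modulator_ratio == 0))
    ak_validation_error("at least one control condition (modulator_ratio = 0) is required")
  set.seed(config$seed)
  ob <- .make_objective(traces, meta, hypothesis$target, config)
  n_par <- ob$n_base + ob$n_factors
  if (n_par >= ob$n_obs)
    ak_validation_error("more parameters than observations")

  # Staged initialization: base rates on controls, then factors one at a
  # time, then a joint polish -- cheap and close to the global optimum.
  ctrl <- which(meta$modulator_ratio == 0)
  labs <- vapply(traces, `[[`, "", "label")
  ctrl_traces <- traces[labs %in% meta$label[ctrl]]
  ob0 <- .make_objective(ctrl_traces, meta[ctrl, , drop = FALSE], "none",
                         config)
  base_fit <- .local_fit(ob0$rss, ob0$start, ob0$lower, ob0$upper)
  start <- ob$start
  start[seq_len(ob$n_base)] <- base_fit$par[seq_len(ob$n_base)]
  if (ob$n_factors > 0) {
    for (k in seq_len(ob$n_factors)) {
      j <- ob$n_base + k
      fk <- function(x) { p <- start; p[j] <- x; ob$rss(p) }
      start[j] <- stats::optimize(fk, lower = ob$lower[j],
                                  upper = ob$upper[j])$minimum
    }
  }
  best <- .local_fit(ob$rss, start, ob$lower, ob$upper)

  # Basin-hopping around the incumbent.
  stall <- 0L; hops <- 0L
  while (hops < config$n_hops && stall < config$stall_hops) {
    hops <- hops + 1L
    cand <- best$par + stats::rnorm(n_par, 0, config$hop_sd)
    cand <- pmin(pmax(cand, ob$lower), ob$upper)
    trial <- .local_fit(ob$rss, cand, ob$lower, ob$upper)
    if (config$verbose)
      message(sprintf("hop %d: rss %.6g (best %.6g)", hops, trial$value,
                      best$value))
    if (trial$value < best$value - 1e-12 * (1 + best$value)) {
      best <- trial; stall <- 0L
    } else stall <- stall + 1L
  }

  par <- best$par
  kn <- 10^par[1L]; k2 <- 10^par[2L]
  kp <- if (ob$fit_kp) 10^par[3L] else config$centers$k_plus
  base_rates <- rate_constants(kn, kp, k2, config$centers$n_c,
                               config$centers$n_2)
  factors <- rep(1, nrow(meta)); names(factors) <- meta$label
  sens <- rep(NA_real_, nrow(meta)); names(sens) <- meta$label
  warn <- character(0)
  if (ob$n_factors > 0) {
    for (k in seq_len(ob$n_factors)) {
      j <- ob$n_base + k
      i <- ob$perturbed[k]
      factors[i] <- 10^par[j]
      d <- log10(sqrt(2))
      up <- par; up[j] <- par[j] + d
      dn <- par; dn[j] <- par[j] - d
      sens[i] <- (ob$rss(up) + ob$rss(dn) - 2 * best$value) /
        (best$value + 1e-12)
      if (sens[i] < 0.01)
        warn <- c(warn, sprintf(
          "factor for condition '%s' is effectively unidentifiable (curvature score %.2g)",
          meta$label[i], sens[i]))
    }
  }
  rss <- best$value
  n <- ob$n_obs
  aic <- n * log(rss / n) + 2 * (n_par + 1)
  structure(list(base_rates = base_rates, fitted_factors = factors,
                 apparent_rate_ratio = .apparent_rate_ratio(hypothesis$target,
                                                            factors),
                 factor_sensitivity = sens, rss = rss, aic = aic,
                 n_obs = n, n_params = n_par, converged = best$converged,
                 seed = config$seed, hypothesis = hypothesis$target,
                 conditions = meta, hops_used = hops, par = par,
                 warnings = warn),
            class = "amylokin_fit")
}

#' @export
print.amylokin_fit <- function(x, ...) {
  cat(sprintf("Global kinetic fit (hypothesis: %s)\n", x$hypothesis))
  cat(sprintf("  rss = %.6g over %d points, %d parameters; AIC = %.2f; %s\n",
              x$rss, x$n_obs, x$n_params, x$aic,
              if (x$converged) "converged" else "NOT converged"))
  cat(sprintf("  base products: k+k2 = %.4g, k+kn = %.4g\n",
              x$base_rates$k_plus * x$base_rates$k_2,
              x$base_rates$k_plus * x$base_rates$k_n))
  ft <- x$fitted_factors[x$conditions$modulator_ratio > 0]
  if (length(ft))
    cat("  fold-changes:",
        paste(sprintf("%s = %.3g", names(ft), ft), collapse = ", "), "\n")
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Rank mechanistic hypotheses by information criterion
#'
#' Fits each hypothesis to the same trace set with [fit_global()] and ranks
#' by AIC (ascending); ties are broken by fewer parameters, then by
#' declaration order.  A hypothesis whose fit fails outright is kept in the
#' table with infinite AIC and ranks last.
#'
#' @param traces list of normalized [kinetic_trace] objects.
#' @param hypotheses list of [perturbation_hypothesis] objects (>= 2).
#' @param config a [fit_config].
#' @return An object of class `amylokin_ranking`: list with `fits` and a
#'   `ranking` data frame (hypothesis, n_params, rss, aic, delta_aic, rank).
#' @export
compare_hypotheses <- function(traces, hypotheses, config = fit_config()) {
  if (length(hypotheses) < 2L)
    ak_validation_error("supply at least two hypotheses to compare")
  fits <- lapply(hypotheses, function(h)
    tryCatch(fit_global(traces, h, config), error = function(e) {
      structure(list(hypothesis = h$target, rss = Inf, aic = Inf,
                     n_params = NA_integer_, converged = FALSE,
                     error = conditionMessage(e)),
                class = "amylokin_fit")
    }))
  tab <- data.frame(
    hypothesis = vapply(fits, `[[`, "", "hypothesis"),
    n_params = vapply(fits, function(f)
      if (is.null(f$n_params) || is.na(f$n_params)) .Machine$integer.max
      else f$n_params, 0L),
    rss = vapply(fits, `[[`, 0, "rss"),
    aic = vapply(fits, `[[`, 0, "aic"),
    declared = seq_along(fits))
  ord <- order(tab$aic, tab$n_params, tab$declared)
  tab <- tab[ord, , drop = FALSE]
  tab$delta_aic <- tab$aic - tab$aic[1L]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  structure(list(fits = fits[ord], ranking = tab),
            class = "amylokin_ranking")
}

#' @export
print.amylokin_ranking <- function(x, ...) {
  cat("Hypothesis ranking (AIC ascending):\n")
  print(x$ranking[, c("rank", "hypothesis", "n_params", "rss", "aic",
                      "delta_aic")], row.names = FALSE)
  invisible(x)
}

#' Half-time dose-response summary
#'
#' Computes the half-time of every trace and summarizes per condition
#' (mean and standard error over replicates).  Traces that never reach the
#' half-signal level are excluded and counted.
#'
#' @param traces list of normalized [kinetic_trace] objects.
#' @return A data frame with columns `condition`, `modulator_ratio`, `n`,
#'   `t50_mean`, `t50_sem` and `n_excluded`, ordered by modulator dose.
#' @export
halftime_dose_response <- function(traces) {
  meta <- .condition_table(traces)
  labs <- vapply(traces, `[[`, "", "label")
  out <- lapply(seq_len(nrow(meta)), function(i) {
    ix <- which(labs == meta$label[i])
    t50 <- vapply(ix, function(j)
      tryCatch(half_time(traces[[j]]),
               amylokin_incomplete_reaction = function(e) NA_real_),
      0)
    ok <- t50[!is.na(t50)]
    n_exc <- sum(is.na(t50))
    if (n_exc > 0)
      message(sprintf("condition '%s': %d incomplete trace(s) excluded",
                      meta$label[i], n_exc))
    data.frame(condition = meta$label[i],
               modulator_ratio = meta$modulator_ratio[i],
               n = length(ok),
               t50_mean = if (length(ok)) mean(ok) else NA_real_,
               t50_sem = if (length(ok) > 1L) stats::sd(ok) / sqrt(length(ok))
                         else if (length(ok) == 1L) NA_real_ else NA_real_,
               n_excluded = n_exc, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
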