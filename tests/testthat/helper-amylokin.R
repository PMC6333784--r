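# Shared fixtures built in code.

# Normalized model signal as a plate reader would report it after per-trace
# normalization: seed mass at t = 0 is part of the baseline.
tht_signal <- function(t_grid, rates, cond, ...) {
  f <- mass_fraction_closed_form(t_grid, rates, cond, ...)$values
  f0 <- cond$M0 / cond$m_total
  (f - f0) / (1 - f0)
}

# Half-time of the model under given rates/conditions.
model_t50 <- function(rates, cond, t_max = 8, n = 3000) {
  tg <- seq(0, t_max, length.out = n)
  half_time(kinetic_trace(tg, tht_signal(tg, rates, cond),
                          normalized = TRUE))
}

# A clean normalized sigmoid with exactly flat 0/1 ends (so that window
# averaging recovers baseline 0 and plateau 1 exactly).
unit_sigmoid_trace <- function(n = 100, t_max = 10, midpoint = 5,
                               steepness = 2, label = "sigmoid") {
  tg <- seq(0, t_max, length.out = n)
  v <- 1 / (1 + exp(-steepness * (tg - midpoint)))
  v <- (v - v[1]) / (v[n] - v[1])
  flat <- max(2L, ceiling(0.15 * n))
  v[seq_len(flat)] <- 0
  v[seq.int(n - flat + 1L, n)] <- 1
  kinetic_trace(tg, v, label = label, normalized = TRUE)
}

# Small noiseless dose series on the secondary pathway.
dose_series_traces <- function(factors = c(1, 1.5, 2.5, 5), noise_sd = 0,
                               replicates = 1, n_points = 120, t_max = 5,
                               seed = 42, seed_fraction = 0,
                               target = "secondary_product",
                               rates = abeta42_rates()) {
  labs <- sprintf("dose_%g", factors)
  conds <- data.frame(label = labs, m_total = 2,
                      seed_fraction = seed_fraction,
                      modulator_ratio = c(0, seq_along(factors[-1])),
                      stringsAsFactors = FALSE)
  f <- factors[-1]
  names(f) <- labs[-1]
  spec <- generator_spec(rates, conds,
                         perturbation_hypothesis(target, f),
                         noise_sd = noise_sd, replicates = replicates,
                         t_max = t_max, n_points = n_points, seed = seed)
  generate_tht_traces(spec)
}

fast_config <- function(seed = 0, n_hops = 2, stall_hops = 2)
  fit_config(seed = seed, n_hops = n_hops, stall_hops = stall_hops,
             quad_nodes = 800)
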