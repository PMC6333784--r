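test_that("noise-free control data are fit to machine precision and products recovered", {
  out <- dose_series_traces(factors = 1, noise_sd = 0, n_points = 100,
                            t_max = 5)
  fit <- fit_global(out$traces, perturbation_hypothesis("none"),
                    fast_config(n_hops = 0))
  expect_lt(fit$rss, 1e-8)
  true <- abeta42_rates()
  expect_lt(abs(fit$base_rates$k_plus * fit$base_rates$k_2 /
                  (true$k_plus * true$k_2) - 1), 0.01)
  expect_lt(abs(fit$base_rates$k_plus * fit$base_rates$k_n /
                  (true$k_plus * true$k_n) - 1), 0.01)
})

test_that("a planted secondary fold-change is recovered from noisy traces", {
  out <- dose_series_traces(factors = c(1, 3), noise_sd = 0.02,
                            replicates = 2, seed = 11)
  fit <- fit_global(out$traces, perturbation_hypothesis("secondary_product"),
                    fast_config())
  f <- fit$fitted_factors[["dose_3"]]
  expect_lt(abs(f / 3 - 1), 0.15)
  expect_equal(unname(fit$fitted_factors["dose_1"]), 1)
  expect_identical(unname(fit$apparent_rate_ratio["dose_3"]), f)
})

test_that("apparent rate ratios rise monotonically with dose", {
  out <- dose_series_traces(factors = c(1, 1.8, 3.2), noise_sd = 0.02,
                            n_points = 80, t_max = 4, seed = 17)
  fit <- fit_global(out$traces, perturbation_hypothesis("secondary_product"),
                    fast_config())
  arr <- fit$apparent_rate_ratio[order(fit$conditions$modulator_ratio)]
  expect_true(all(diff(arr) > 0))
})

test_that("fits are bit-identical under the same seed", {
  out <- dose_series_traces(factors = c(1, 2.5), noise_sd = 0.02,
                            n_points = 60, t_max = 4, seed = 5)
  f1 <- fit_global(out$traces, perturbation_hypothesis("secondary_product"),
                   fast_config(seed = 123))
  f2 <- fit_global(out$traces, perturbation_hypothesis("secondary_product"),
                   fast_config(seed = 123))
  expect_identical(f1$par, f2$par)
  expect_identical(f1$rss, f2$rss)
  expect_identical(f1$fitted_factors, f2$fitted_factors)
})

test_that("hypothesis ranking is by AIC with deterministic tie-breaking", {
  out <- dose_series_traces(factors = c(1, 4), noise_sd = 0.02,
                            n_points = 60, t_max = 4, seed = 9)
  cmp <- compare_hypotheses(out$traces,
                            list(perturbation_hypothesis("secondary_product"),
                                 perturbation_hypothesis("k2_only"),
                                 perturbation_hypothesis("none")),
                            fast_config(n_hops = 0))
  tab <- cmp$ranking
  # the two identical parameterizations tie exactly; declaration order decides
  expect_equal(tab$aic[tab$hypothesis == "secondary_product"],
               tab$aic[tab$hypothesis == "k2_only"])
  expect_lt(tab$rank[tab$hypothesis == "secondary_product"],
            tab$rank[tab$hypothesis == "k2_only"])
  # the null model cannot absorb a strong perturbation: worst rank
  expect_identical(tab$hypothesis[nrow(tab)], "none")
  expect_gt(tab$rss[tab$hypothesis == "none"],
            tab$rss[tab$hypothesis == "secondary_product"])
})

test_that("half-time dose-response summarizes replicates and excludes incomplete traces", {
  tr <- unit_sigmoid_trace()
  tr$m_total <- 2; tr$seed_fraction <- 0; tr$modulator_ratio <- 0
  reps <- lapply(1:3, function(i) { x <- tr; x$replicate <- i; x })
  dr <- halftime_dose_response(reps)
  expect_identical(dr$t50_sem, 0)
  expect_identical(dr$n, 3L)

  out <- dose_series_traces(factors = c(1, 1.5, 2.5, 5), noise_sd = 0)
  dr2 <- halftime_dose_response(out$traces)
  dr2 <- dr2[order(dr2$modulator_ratio), ]
  expect_true(all(diff(dr2$t50_mean) < 0))

  # an incomplete trace is excluded with a logged count
  stall <- kinetic_trace(tr$times, tr$values * 0.4, label = "sigmoid",
                         normalized = TRUE, replicate = 4, m_total = 2,
                         seed_fraction = 0, modulator_ratio = 0)
  expect_message(dr3 <- halftime_dose_response(c(reps, list(stall))),
                 "incomplete")
  expect_identical(dr3$n_excluded, 1L)
  expect_identical(dr3$n, 3L)
})

test_that("a k2 factor under elongation-dominated seeding is flagged unidentifiable", {
  # heavy seeding + weak secondary pathway: the data contain almost no
  # information about k2, so its fold-change must carry a warning
  weak <- rate_constants(k_n = 1.8e-7, k_plus = 975, k_2 = 1e-6)
  out <- dose_series_traces(factors = c(1, 5), noise_sd = 0.005,
                            seed_fraction = 0.25, target = "k2_only",
                            t_max = 2, n_points = 80, seed = 3,
                            rates = weak)
  fit <- fit_global(out$traces, perturbation_hypothesis("k2_only"),
                    fit_config(seed = 0, n_hops = 0, quad_nodes = 800,
                               centers = weak))
  expect_true(length(fit$warnings) > 0)
  expect_match(fit$warnings[1], "unidentifiable")
})

test_that("factor identifiability degrades from 5% to 25% seeding", {
  fx <- make_paper_fixture(seed = 77, replicates = 1)
  cfg <- fast_config(n_hops = 1)
  f5 <- fit_global(fx$traces$seeded_5, perturbation_hypothesis("k2_only"), cfg)
  f25 <- fit_global(fx$traces$seeded_25, perturbation_hypothesis("k2_only"),
                    cfg)
  s5 <- f5$factor_sensitivity[!is.na(f5$factor_sensitivity)]
  s25 <- f25$factor_sensitivity[!is.na(f25$factor_sensitivity)]
  expect_true(all(s25 < s5))
})
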