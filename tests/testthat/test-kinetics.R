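ref_rates <- function() rate_constants(k_n = 1e-7, k_plus = 1e3, k_2 = 1)
unseeded2 <- function() reaction_conditions(2)

test_that("closed form depends on the rates only through k+k2 and k+kn (unseeded)", {
  tg <- seq(0, 3, length.out = 150)
  r1 <- ref_rates()
  r2 <- rate_constants(k_n = r1$k_n / 2, k_plus = 2 * r1$k_plus,
                       k_2 = r1$k_2 / 2)
  f1 <- mass_fraction_closed_form(tg, r1, unseeded2())
  f2 <- mass_fraction_closed_form(tg, r2, unseeded2())
  expect_lt(max(abs(f1$values - f2$values)), 1e-9)
  d1 <- derive_parameters(r1, unseeded2())
  d2 <- derive_parameters(r2, unseeded2())
  for (nm in c("kappa", "lambda", "C_plus", "C_minus", "B_plus", "B_minus",
               "k_inf", "k_inf_tilde"))
    expect_equal(d1[[nm]], d2[[nm]], tolerance = 1e-12)
})

test_that("no nucleation source returns a flat sentinel curve, not an error", {
  tg <- seq(0, 2, length.out = 50)
  tr <- mass_fraction_closed_form(tg, rate_constants(0, 1e3, 5), unseeded2())
  expect_identical(attr(tr, "flag"), "no nucleation source")
  expect_true(all(tr$values == 0))
  dp <- derive_parameters(rate_constants(0, 1e3, 5), unseeded2())
  expect_identical(dp$flag, "no nucleation source")
})

test_that("closed form reproduces the moment-equation oracle on the reference set", {
  # reference set: m0 = 2 uM, n_c = n_2 = 2, k+kn = 1e-4, k+k2 = 1e3
  r <- rate_constants(k_n = 1e-7, k_plus = 1e3, k_2 = 1)
  tg <- seq(0, 3, length.out = 200)
  cf <- mass_fraction_closed_form(tg, r, unseeded2(), method = "fixed_point")
  om <- integrate_moments(r, unseeded2(), tg[-1])
  expect_lt(max(abs(cf$values[-1] - om$M / 2)), 0.01)
  # quadrature route is an order of magnitude closer still
  cq <- mass_fraction_closed_form(tg, r, unseeded2(), method = "quadrature")
  expect_lt(max(abs(cq$values[-1] - om$M / 2)), 1e-3)
})

test_that("mass fraction starts at the seed fraction and saturates at 1", {
  r <- ref_rates()
  tr <- mass_fraction_closed_form(c(0, 0.1, 5), r, unseeded2())
  expect_identical(tr$values[1], 0)
  dp <- derive_parameters(r, unseeded2())
  t_big <- 60 / dp$kappa   # kappa * t = 60 > 50
  tr2 <- mass_fraction_closed_form(c(0, t_big, 2 * t_big), r, unseeded2())
  expect_equal(tr2$values[2], 1, tolerance = 1e-9)
  expect_false(any(!is.finite(tr2$values)))
  seeded <- reaction_conditions(2, 0.25)
  tr3 <- mass_fraction_closed_form(c(0, 0.01), r, seeded)
  expect_equal(tr3$values[1], 0.25, tolerance = 1e-9)
  # monotone nondecreasing everywhere
  tg <- seq(0, 4, length.out = 400)
  expect_true(all(diff(mass_fraction_closed_form(tg, r, seeded)$values) >= 0))
})

test_that("moment integration conserves mass and recovers analytic limits", {
  tg <- seq(0.01, 2, length.out = 80)
  # no dynamics at all
  still <- integrate_moments(rate_constants(0, 0, 0),
                             reaction_conditions(2, 0.05), tg)
  expect_true(all(still$m == still$m[1]) && all(still$M == still$M[1]))
  # elongation-only limit: M(t) = M0 + m0 (1 - exp(-2 k+ P0 t))
  cond <- reaction_conditions(2, 0.05, seed_length = 500)
  r <- rate_constants(0, 1e3, 0)
  om <- integrate_moments(r, cond, tg)
  exact <- cond$M0 + cond$m0 * (1 - exp(-2 * 1e3 * cond$P0 * tg))
  expect_lt(max(abs(om$M - exact)), 1e-6)
  expect_lt(max(abs(om$m + om$M - 2)), 2e-6)
  # the quadrature route hits the same limit analytically
  cf <- mass_fraction_closed_form(tg, r, cond, method = "quadrature")
  expect_lt(max(abs(cf$values - exact / 2)), 1e-4)
  # full conversion at long times for the reference set
  om2 <- integrate_moments(ref_rates(), unseeded2(),
                           seq(0.01, 5, length.out = 50))
  expect_lt(2 - om2$M[nrow(om2)], 1e-3 * 2)
})

test_that("half_time interpolates the first crossing of 0.5", {
  tr <- kinetic_trace(seq(0, 2, length.out = 9),
                      c(0, 0.05, 0.1, 0.2, 0.5, 0.8, 0.95, 1, 1),
                      normalized = TRUE)
  expect_identical(half_time(tr), 1.0)   # exact grid-point crossing
  # linear interpolation between brackets
  tr2 <- kinetic_trace(0:7, c(0, 0, 0.2, 0.4, 0.6, 0.9, 1, 1),
                       normalized = TRUE)
  expect_equal(half_time(tr2), 3.5)
  expect_error(half_time(kinetic_trace(1:8, rep(0.2, 8), normalized = TRUE)),
               "incomplete reaction",
               class = "amylokin_incomplete_reaction")
})

test_that("half-time of the integrated trace matches root-finding on the closed form", {
  r <- ref_rates(); cond <- unseeded2()
  tg <- seq(0.001, 1, length.out = 2000)
  om <- integrate_moments(r, cond, tg)
  t50_ode <- half_time(kinetic_trace(tg, om$M / 2, normalized = TRUE,
                                     label = "ode"))
  f <- function(t) mass_fraction_closed_form(c(0, t), r, cond,
                                             method = "quadrature")$values[2] - 0.5
  t50_root <- stats::uniroot(f, c(0.01, 1), tol = 1e-10)$root
  expect_lt(abs(t50_ode - t50_root) / t50_root, 0.005)
})

test_that("length scaling law: ratio is sqrt(factor_kplus / factor_k2)", {
  expect_identical(predicted_length_scale(1, 1), 1)
  expect_equal(predicted_length_scale(5, 1), 1 / sqrt(5))
  expect_equal(predicted_length_scale(1, 4), 2)
  expect_error(predicted_length_scale(0, 1), "positive",
               class = "amylokin_validation_error")
  expect_error(predicted_length_scale(5, -1), "positive",
               class = "amylokin_validation_error")
})

test_that("plateau M/P from the moment equations tracks the length scaling", {
  r <- ref_rates(); cond <- unseeded2()
  tg <- seq(0.01, 6, length.out = 60)
  ctl <- integrate_moments(r, cond, tg)
  trt <- integrate_moments(rate_constants(r$k_n, r$k_plus, 5 * r$k_2),
                           cond, tg)
  mean_len <- function(om) om$M[nrow(om)] / om$P[nrow(om)]
  ratio <- mean_len(trt) / mean_len(ctl)
  expect_lt(abs(ratio - 1 / sqrt(5)) / (1 / sqrt(5)), 0.15)
})

test_that("closed form tracks the oracle across seed fractions and rate products", {
  grid <- expand.grid(kpk2 = c(1e2, 1e4), kpkn = c(1e-5, 1e-3),
                      s = c(0, 0.05, 0.25))
  for (i in seq_len(nrow(grid))) {
    r <- rate_constants(k_n = grid$kpkn[i] / 1e3, k_plus = 1e3,
                        k_2 = grid$kpk2[i] / 1e3)
    cond <- reaction_conditions(2, grid$s[i])
    kap <- derive_parameters(r, cond)$kappa
    tg <- seq(30 / kap / 299, 30 / kap, length.out = 299)
    om <- integrate_moments(r, cond, tg)
    cf <- mass_fraction_closed_form(tg, r, cond)
    expect_lt(max(abs(cf$values - om$M / 2)), 0.01)
  }
})

test_that("half-time decreases strictly with k2 and loses sensitivity at high seed", {
  r <- abeta42_rates()
  t50_u <- vapply(c(1, 1.5, 2.5, 5), function(f)
    model_t50(rate_constants(r$k_n, r$k_plus, f * r$k_2),
              reaction_conditions(2)), 0)
  expect_true(all(diff(t50_u) < 0))
  # k2 five-fold: relative half-time change shrinks as seeding grows
  rel_change <- vapply(c(0, 0.05, 0.25), function(s) {
    cond <- reaction_conditions(2, s)
    1 - model_t50(rate_constants(r$k_n, r$k_plus, 5 * r$k_2), cond) /
      model_t50(r, cond)
  }, 0)
  expect_true(all(diff(rel_change) < 0))
})
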