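afm_heights <- function(v, condition = "s")
  fibril_measurements(v, dimension = "height", modality = "AFM",
                      condition = condition)

test_that("dimension summaries follow the total-error convention", {
  s <- summarize_dimensions(afm_heights(1:5))
  expect_identical(s$n, 5L)
  expect_identical(s$mean, 3)
  expect_identical(s$median, 3)
  expect_equal(s$sem, sd(1:5) / sqrt(5))
  expect_equal(s$total_error, sd(1:5) / sqrt(5) + 0.15)
  expect_true(s$q1 <= s$median && s$median <= s$q3)

  const <- summarize_dimensions(afm_heights(rep(3, 10)))
  expect_identical(const$sd, 0)
  expect_identical(const$sem, 0)
  expect_identical(const$total_error, 0.15)

  expect_error(summarize_dimensions(afm_heights(4.2)), "at least two",
               class = "amylokin_validation_error")
  expect_error(fibril_measurements(c(1, -2), "height", "AFM"), "positive",
               class = "amylokin_validation_error")
})

test_that("default sensitivity floors: AFM 0.05+0.1 nm, TEM 0.7 nm", {
  expect_identical(default_sensitivity("AFM", "height"), 0.15)
  expect_identical(default_sensitivity("TEM", "width"), 0.7)
  expect_identical(default_sensitivity("AFM", "length"), 0.01)
  expect_identical(afm_heights(1:3)$sensitivity_error, 0.15)
})

test_that("total error is nonincreasing in n at fixed spread", {
  sds <- vapply(c(10, 40, 160, 640), function(n) {
    v <- rep(c(2, 4), length.out = n)   # fixed sd, growing n
    summarize_dimensions(afm_heights(v))$total_error
  }, 0)
  expect_true(all(diff(sds) <= 0))
})

test_that("condition comparison is shifted by the sensitivity floor", {
  set.seed(31)
  a <- afm_heights(rnorm(50, 6.3, 1), "treated")
  b <- afm_heights(rnorm(50, 4.2, 1), "control")
  res <- compare_conditions(a, b)
  # closed-form check: t = (|diff| - 0.15) / se
  se <- sqrt(var(a$values) / 50 + var(b$values) / 50)
  t_expect <- (abs(mean(a$values) - mean(b$values)) - 0.15) / se
  expect_equal(abs(res$t), t_expect, tolerance = 1e-10)
  expect_lt(res$p, 0.001)
  expect_identical(res$stars, "***")

  # identical samples: no significance
  v <- rnorm(30, 5, 0.5)
  expect_false(compare_conditions(afm_heights(v + 1e-12),
                                  afm_heights(v))$significant)

  # a difference exactly at the floor is attributed to the instrument
  x <- rnorm(5000, 5, 0.3)
  shifted <- compare_conditions(afm_heights(x + 0.15), afm_heights(x))
  expect_false(shifted$significant)
  expect_equal(shifted$p, 1, tolerance = 1e-6)
})

test_that("zero sensitivity reduces to the standard Welch test", {
  set.seed(13)
  for (i in 1:5) {
    a <- rnorm(20 + i, 5 + 0.1 * i, 0.8)
    b <- rnorm(25, 5, 1.1)
    ours <- compare_conditions(
      fibril_measurements(a, "height", "AFM", sensitivity_error = 0),
      fibril_measurements(b, "height", "AFM", sensitivity_error = 0))
    ref <- t.test(a, b)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
    expect_equal(abs(ours$t), abs(unname(ref$statistic)), tolerance = 1e-12)
  }
})

test_that("mismatched dimension or modality is rejected", {
  a <- fibril_measurements(1:5, "height", "AFM")
  b <- fibril_measurements(1:5, "width", "TEM")
  expect_error(compare_conditions(a, b), "differ",
               class = "amylokin_validation_error")
})

test_that("length ratio propagates total errors and is exact on identical sets", {
  lens <- fibril_measurements(c(1.2, 1.8, 2.1, 1.5, 2.4), "length", "AFM")
  lr <- length_ratio(lens, lens)
  expect_identical(lr$ratio, 1)
  s <- summarize_dimensions(lens)
  expect_equal(lr$error, sqrt(2) * s$total_error / s$mean)
})

test_that("propagated ratio error agrees with a bootstrap within 20%", {
  set.seed(101)
  trt <- generate_fibril_dimensions(100, log(0.63) - 0.55^2 / 2, 0.55,
                                    seed = 1, condition = "treated")
  ctl <- generate_fibril_dimensions(100, log(1.81) - 0.55^2 / 2, 0.55,
                                    seed = 2, condition = "control")
  lr <- length_ratio(trt, ctl)
  B <- 1e4
  bt <- matrix(sample(trt$values, B * 100, replace = TRUE), nrow = B)
  bc <- matrix(sample(ctl$values, B * 100, replace = TRUE), nrow = B)
  boot_sd <- sd(rowMeans(bt) / rowMeans(bc))
  # remove the (tiny) sensitivity floor from the propagated error before
  # comparing with the purely statistical bootstrap spread
  st <- summarize_dimensions(trt); sc <- summarize_dimensions(ctl)
  stat_err <- lr$ratio * sqrt((st$sem / st$mean)^2 + (sc$sem / sc$mean)^2)
  expect_lt(abs(stat_err - boot_sd) / boot_sd, 0.2)
})

test_that("scaling consistency verdicts", {
  expect_true(scaling_consistency(0.348, 5, 1, 0.15)$consistent)
  expect_false(scaling_consistency(1.0, 5, 1, 0.15)$consistent)
  expect_true(scaling_consistency(1 / sqrt(5), 5, 1, 0)$consistent)
})

test_that("morphometry CSV round-trips and validates", {
  msets <- list(
    a = fibril_measurements(c(1.2, 1.5, 0.9), "length", "AFM",
                            condition = "control"),
    b = fibril_measurements(c(11, 13, 12.5), "width", "TEM",
                            condition = "control"))
  p <- withr::local_tempfile(fileext = ".csv")
  write_morphometry_csv(msets, p)
  back <- read_morphometry_csv(p)
  expect_length(back, 2)
  key <- "control_AFM_length"
  expect_equal(back[[key]]$values, msets$a$values, tolerance = 1e-12)
  expect_identical(back[[key]]$unit, "um")

  bad <- data.frame(condition = "c", modality = "AFM", dimension = "height",
                    value = c(4, -1), unit = c("nm", "nm"))
  pb <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(bad, pb, row.names = FALSE)
  expect_error(read_morphometry_csv(pb), "rows 2",
               class = "amylokin_validation_error")
  bad$value <- c(4, 5); bad$unit <- c("nm", "km")
  utils::write.csv(bad, pb, row.names = FALSE)
  expect_error(read_morphometry_csv(pb), "unit",
               class = "amylokin_validation_error")
})
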