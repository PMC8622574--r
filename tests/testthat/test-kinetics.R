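test_that("fractional conversion model has the right anchors and monotonicity", {
  expect_equal(fractional_conversion(0, 78.4, 196.4, 0.027), 78.4)
  expect_equal(fractional_conversion(1e9, 78.4, 196.4, 0.027), 196.4)
  expect_equal(fractional_conversion(60, 78.4, 196.4, 0.027),
               196.4 - 118 * exp(-1.62), tolerance = 1e-10)

  t <- seq(0, 240, by = 5)
  s <- fractional_conversion(t, 100, 300, 0.02)
  expect_true(all(diff(s) > 0))
  expect_true(all(s >= 100 & s <= 300))

  expect_error(fractional_conversion(10, 100, 300, -0.1),
               class = "beanbolus_parameter_error")
  expect_error(fractional_conversion(10, 100, 50, 0.02),
               class = "beanbolus_parameter_error")
})

test_that("fractional conversion fitting recovers generators and beats the grid oracle", {
  tp <- c(0, 20, 30, 40, 60, 90, 120, 180, 240)
  series <- simulate_digesta("fractional_conversion",
                             params = list(s0 = 78.4, sf = 196.4, ks = 0.027),
                             timepoints = tp)
  fit <- fit_fractional_conversion(series)
  expect_true(fit$converged)
  expect_lt(abs(fit$params[["s0"]] - 78.4) / 78.4, 0.005)
  expect_lt(abs(fit$params[["sf"]] - 196.4) / 196.4, 0.005)
  expect_lt(abs(fit$params[["ks"]] - 0.027) / 0.027, 0.005)

  # 5-point toy series vs exhaustive 3-D grid search
  toy_t <- c(0, 30, 60, 120, 240)
  toy_v <- c(52, 95, 121, 148, 160) # hand-picked, roughly saturating
  fit2 <- fit_fractional_conversion(tibble::tibble(time_min = toy_t,
                                                   value_mg = toy_v))
  oracle <- fc_grid_oracle(toy_t, toy_v, c(20, 90), c(120, 220), c(0.002, 0.08))
  expect_lte(sum((toy_v - fit2$data$predicted)^2), oracle$rss + 1e-8)
  expect_equal(fit2$params[["ks"]], oracle$ks, tolerance = 0.01)
  expect_equal(fit2$params[["sf"]], oracle$sf, tolerance = 0.01)

  expect_error(
    fit_fractional_conversion(tibble::tibble(time_min = c(0, 10, 20),
                                             value_mg = c(1, 2, 3))),
    class = "beanbolus_fit_error"
  )
  expect_error(
    fit_fractional_conversion(tibble::tibble(time_min = tp,
                                             value_mg = seq(200, 40, length.out = 9))),
    class = "beanbolus_fit_error"
  )
  # constant series: degenerate, must not report a spurious rate
  const <- fit_fractional_conversion(tibble::tibble(time_min = tp,
                                                    value_mg = rep(100, 9)))
  expect_lt(const$params[["sf"]] - const$params[["s0"]], 1)
})

test_that("noisy replicate recovery of the digestion rate stays within bounds", {
  tp <- c(0, 20, 30, 40, 60, 90, 120, 180, 240)
  errs <- withr::with_seed(52, vapply(1:200, function(i) {
    v <- fractional_conversion(tp, 90.5, 240.0, 0.023) + rnorm(9, 0, 5)
    fit <- fit_fractional_conversion(tibble::tibble(time_min = tp, value_mg = v))
    c(abs(fit$params[["ks"]] - 0.023) / 0.023,
      abs(fit$params[["sf"]] - 240.0) / 240.0)
  }, numeric(2)))
  expect_lte(median(errs[1, ]), 0.10)   # rate constant
  expect_lte(median(errs[2, ]), 0.03)   # plateau
})

test_that("zero-order fitting is the closed-form least-squares line", {
  exact <- tibble::tibble(time_min = c(0, 30, 60, 120, 240),
                          value_mg = 100 + 0.1 * c(0, 30, 60, 120, 240))
  fit <- fit_zero_order(exact)
  expect_equal(fit$params[["p0"]], 100)
  expect_equal(fit$params[["kp"]], 0.1)
  expect_equal(fit$adj_r2, 1)

  expect_equal(fit_zero_order(tibble::tibble(
    time_min = c(0, 5, 10), value_mg = c(0, 0.5, 1)
  ))$params[["kp"]], 0.1)

  # identical to the normal-equation oracle on a noisy series
  noisy <- simulate_digesta("zero_order", params = list(p0 = 30, kp = 0.08),
                            noise_sd = 2, seed = 13)
  nf <- fit_zero_order(noisy)
  beta <- normal_equations_oracle(cbind(1, noisy$time_min), noisy$value_mg)
  expect_equal(unname(nf$params), unname(beta), tolerance = 1e-10)

  # unbiased slope across replicates, each within 3 standard errors
  withr::with_seed(61, {
    slopes <- vapply(1:500, function(i) {
      s <- simulate_digesta("zero_order", params = list(p0 = 30, kp = 0.08),
                            noise_sd = 2)
      fit_zero_order(s)$params[["kp"]]
    }, numeric(1))
  })
  t <- c(0, 20, 30, 40, 60, 90, 120, 180, 240)
  se <- 2 / sqrt(sum((t - mean(t))^2))
  expect_gte(mean(abs(slopes - 0.08) < 3 * se), 0.99)
  expect_lt(abs(mean(slopes) - 0.08), se / 5)

  expect_error(fit_zero_order(tibble::tibble(time_min = c(0, 10),
                                             value_mg = c(1, 2))),
               class = "beanbolus_fit_error")
})

test_that("starch fractions implement the conversion identity and conserve mass", {
  expect_identical(starch_conversion_factor(), 162 / 180)
  expect_identical(starch_conversion_factor(), 0.9)

  fr <- starch_fractions(g20 = 10, g120 = 10, total_starch = 90)
  expect_equal(fr$rds, 10)
  expect_equal(fr$sds, 0)
  expect_equal(fr$rs, 90)

  # full digestion bound
  full <- starch_fractions(g20 = 100 / 0.9, g120 = 100 / 0.9, total_starch = 100)
  expect_equal(full$rds, 100)
  expect_equal(full$rs, 0, tolerance = 1e-9)

  # conservation across random valid inputs
  withr::with_seed(71, {
    for (i in 1:50) {
      ts <- runif(1, 50, 500)
      g120 <- runif(1, 0, ts / 0.9)
      g20 <- runif(1, 0, g120)
      f <- starch_fractions(g20, g120, ts)
      expect_equal(f$rds + f$sds + f$rs, 100, tolerance = 1e-9)
      expect_true(all(c(f$rds, f$sds, f$rs) >= -1e-9))
    }
  })

  expect_error(starch_fractions(10, 5, 90), class = "beanbolus_parameter_error")
  expect_error(starch_fractions(10, 20, 0), class = "beanbolus_parameter_error")
  expect_error(starch_fractions(10, 200, 90), class = "beanbolus_parameter_error")
  expect_error(resistant_fraction(60, 50), class = "beanbolus_parameter_error")
})

test_that("gastric endpoints are returned descriptively, never fitted", {
  s <- tibble::tibble(time_min = c(0, 120), value_mg = c(12, 30),
                      phase = "gastric", analyte = "glucose")
  ep <- gastric_endpoints(s)
  expect_equal(ep$value_0, 12)
  expect_equal(ep$value_120, 30)
  expect_error(gastric_endpoints(tibble::tibble(time_min = 0, value_mg = 12)),
               class = "beanbolus_parameter_error")

  gen <- simulate_digesta("zero_order", params = list(p0 = 12, kp = 0.15),
                          timepoints = c(0, 120), phase = "gastric")
  expect_equal(gastric_endpoints(gen)$value_120, 12 + 0.15 * 120)
})

test_that("fit diagnostics report adjusted R-squared, residuals and parity", {
  # hand-computed adjusted R^2 for a 5-point zero-order fit:
  # slope 2.4, intercept 1.6, SSres 1.6, SStot 59.2 -> adj R^2 = 0.9459459...
  s <- tibble::tibble(time_min = 0:4, value_mg = c(2, 4, 6, 8, 12))
  fit <- fit_zero_order(s)
  expect_equal(fit$adj_r2, 1 - (1 - (1 - 1.6 / 59.2)) * 4 / 2, tolerance = 1e-12)

  d <- fit_diagnostics(fit)
  expect_equal(d$adj_r2, fit$adj_r2)
  expect_equal(d$residuals$residual, c(0.4, 0, -0.4, -0.8, 0.8), tolerance = 1e-12)
  expect_equal(d$parity$observed, s$value_mg)

  # perfect fit: unit adjusted R^2 and zero residuals
  perfect <- fit_zero_order(tibble::tibble(time_min = 0:4,
                                           value_mg = 5 + 2 * (0:4)))
  expect_equal(perfect$adj_r2, 1)
  expect_true(all(abs(augment(perfect)$residual) < 1e-12))
})
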