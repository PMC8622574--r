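test_that("inverse-CDF sampler reproduces the Rosin-Rammler law", {
  # forced-quantile identities via the quantile function the sampler uses
  expect_equal(rr_quantile(0.5, x50 = 5, b = 1.63), 5)
  expect_equal(rr_quantile(0, x50 = 5, b = 1.63), 0)

  # Kolmogorov distance of the empirical CDF of 1e5 draws vs the model
  a <- sample_rosin_rammler(1e5, x50 = 5.2, b = 1.6, seed = 99)
  ks <- max(abs(seq_along(a) / length(a) - rr_cdf(sort(a), 5.2, 1.6)))
  expect_lt(ks, 0.01)

  # area-weighted empirical median of a large sample vs the closed-form
  # quantile of the size-biased distribution, checked within 2 percent
  sa <- sort(a)
  emp_med <- sa[which(cumsum(sa) / sum(sa) >= 0.5)[1]]
  wq <- function(p) {
    g <- seq(1e-4, max(a), length.out = 2e5)
    dens <- g * diff(c(0, rr_cdf(g, 5.2, 1.6)))
    g[which(cumsum(dens) / sum(dens) >= p)[1]]
  }
  expect_lt(abs(emp_med - wq(0.5)) / wq(0.5), 0.02)

  expect_error(sample_rosin_rammler(10, -1, 1.6), class = "beanbolus_parameter_error")
  expect_error(sample_rosin_rammler(10, 5, 0), class = "beanbolus_parameter_error")
  expect_identical(sample_rosin_rammler(50, 5, 1.6, seed = 3),
                   sample_rosin_rammler(50, 5, 1.6, seed = 3))
})

test_that("digestion-curve generator evaluates both models exactly at zero noise", {
  fc <- simulate_digesta("fractional_conversion",
                         params = list(s0 = 78.4, sf = 196.4, ks = 0.027))
  expect_equal(fc$value_mg[fc$time_min == 0], 78.4)
  expect_true(all(diff(fc$value_mg) > 0))        # monotone towards the plateau
  expect_true(all(fc$value_mg < 196.4))

  zo <- simulate_digesta("zero_order", params = list(p0 = 50, kp = 0.1),
                         timepoints = c(0, 60, 120, 240))
  expect_equal(zo$value_mg[zo$time_min == 240], 74)

  expect_error(simulate_digesta("zero_order", params = list(p0 = 50, kp = 0.1),
                                noise_sd = -1),
               class = "beanbolus_parameter_error")
  expect_error(simulate_digesta("zero_order", params = list(p0 = 50, kp = 0.1),
                                timepoints = c(10, 5)),
               class = "beanbolus_parameter_error")
  expect_identical(
    simulate_digesta("fractional_conversion",
                     params = list(s0 = 50, sf = 150, ks = 0.02),
                     noise_sd = 5, seed = 7),
    simulate_digesta("fractional_conversion",
                     params = list(s0 = 50, sf = 150, ks = 0.02),
                     noise_sd = 5, seed = 7)
  )
})

test_that("panel generator places groups and hits the target correlation", {
  panel <- simulate_panel(seed = 4)
  expect_equal(nrow(panel), 17 * 3)
  wide <- tidyr::pivot_wider(panel[c("participant_id", "sample", "duration_s",
                                     "designed_class")],
                             names_from = "sample", values_from = "duration_s")
  meds <- vapply(c("A", "B", "C"),
                 function(s) median(panel$duration_s[panel$sample == s]),
                 numeric(1))
  fast <- wide[wide$designed_class == "fast", c("A", "B", "C")]
  slow <- wide[wide$designed_class == "slow", c("A", "B", "C")]
  expect_true(all(t(fast) <= meds))
  expect_true(all(t(slow) > meds))

  # perfect linear link when the target correlation is 1
  p1 <- simulate_panel(target_r = 1, seed = 5)
  per <- dplyr::summarise(p1, d = mean(duration_s), a = amylase_cu_per_ml[1],
                          .by = participant_id)
  expect_equal(pearson_r(per$d, per$a), 1)

  # large panel approaches the requested correlation
  big <- simulate_panel(n_fast = 530, n_slow = 353, n_inconsistent = 117,
                        target_r = 0.88, seed = 6)
  perb <- dplyr::summarise(big, d = mean(duration_s), a = amylase_cu_per_ml[1],
                           .by = participant_id)
  expect_lt(abs(pearson_r(perb$d, perb$a) - 0.88), 0.05)

  expect_error(simulate_panel(n_inconsistent = 1,
                              median_anchor_s = c(A = 28.5), seed = 1),
               class = "beanbolus_spec_error")
  expect_identical(simulate_panel(seed = 8), simulate_panel(seed = 8))
})

test_that("plate renderer honours requested areas, counts and determinism", {
  # single-particle plate: rendered area within 2 percent of the request
  one <- simulate_plate(plate_spec(n_white = 1, n_black = 0,
                                   rr_white = c(x50 = 10, b = 60),
                                   image_size_px = 700, seed = 31))
  expect_equal(nrow(one$truth), 1)
  expect_lt(abs(one$truth$area_mm2 - one$truth$requested_area_mm2) /
              one$truth$requested_area_mm2, 0.02)

  empty <- simulate_plate(plate_spec(n_white = 0, n_black = 0,
                                     image_size_px = 400, seed = 1))
  expect_equal(nrow(empty$truth), 0)

  # rendered ground-truth areas track the sampled request for >= 2 mm^2 blobs
  fix <- plate_fixture("clean")
  big <- fix$truth[fix$truth$requested_area_mm2 >= 2, ]
  expect_true(all(abs(big$area_mm2 - big$requested_area_mm2) /
                    big$requested_area_mm2 <= 0.02))

  spec <- plate_spec(n_white = 3, n_black = 2, image_size_px = 400, seed = 77)
  expect_identical(simulate_plate(spec)$image, simulate_plate(spec)$image)

  expect_error(simulate_plate(plate_spec(n_white = 4000, n_black = 0,
                                         rr_white = c(x50 = 50, b = 2),
                                         image_size_px = 400, seed = 1)),
               class = "beanbolus_packing_error")
})

test_that("TPA curve generator realises the requested texture parameters", {
  curve <- simulate_tpa_curve(hardness = 12, cohesiveness = 0.6,
                              springiness = 0.9, resilience = 0.7, seed = 1)
  tpa <- compute_tpa(curve)
  expect_equal(tpa$hardness, 12, tolerance = 1e-6)
  expect_equal(tpa$cohesiveness, 0.6, tolerance = 0.01)
  expect_equal(tpa$springiness, 0.9, tolerance = 0.01)
  expect_equal(tpa$resilience, 0.7, tolerance = 0.01)
})
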