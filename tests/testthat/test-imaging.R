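test_that("spatial calibration is the marker length ratio", {
  cal <- calibrate(10, 100)
  expect_equal(cal$mm_per_px, 0.1)
  expect_error(calibrate(0, 100), class = "beanbolus_parameter_error")
  expect_error(calibrate(10, -5), class = "beanbolus_parameter_error")

  # region arithmetic: 400 px at 0.05 mm/px is 1 mm^2
  regions <- tibble::tibble(particle_id = 1L, pixel_count = 400L,
                            centroid_x_px = 1, centroid_y_px = 1,
                            mean_r = 0.5, mean_g = 0.5, mean_b = 0.5,
                            boundary_flag = FALSE)
  expect_equal(measure_areas(regions, calibrate(5, 100))$area_mm2, 1)
  # zero-pixel regions are excluded
  regions0 <- dplyr::mutate(regions, pixel_count = 0L)
  expect_equal(nrow(measure_areas(regions0, calibrate(5, 100))), 0)
  expect_error(measure_areas(regions, "no calibration"),
               class = "beanbolus_calibration_error")
})

test_that("plate isolation finds the blue disc and rejects plateless frames", {
  fix <- plate_fixture("clean")
  mask <- isolate_plate(fix$image)
  d <- dim(fix$image)[1]
  xg <- matrix(rep(seq_len(d), each = d), d)
  yg <- matrix(rep(seq_len(d), times = d), d)
  disc <- (xg - fix$plate$centre_px[1])^2 + (yg - fix$plate$centre_px[2])^2 <=
    fix$plate$radius_px^2
  iou <- sum(mask & disc) / sum(mask | disc)
  expect_gte(iou, 0.98)

  black <- array(0, dim = c(60, 60, 3))
  expect_error(isolate_plate(black), class = "beanbolus_plate_error")

  # plate filling the full frame: the mask is (essentially) the full frame
  full <- array(0, dim = c(80, 80, 3))
  full[, , 1] <- 0.10; full[, , 2] <- 0.30; full[, , 3] <- 0.75
  expect_equal(mean(isolate_plate(full)), 1)
})

test_that("reflection removal deletes small bright blobs and keeps particles", {
  fix <- plate_fixture("reflective")
  cal <- fixture_calibration(fix)
  mask <- isolate_plate(fix$image)
  cleaned <- remove_reflections(fix$image, mask, cal)
  regions <- measure_areas(detect_particles(cleaned, mask), cal)
  recs <- apply_sieve_filter(regions, 1)
  truth_after_sieve <- fix$truth[2 * sqrt(fix$truth$area_mm2 / pi) >= 1, ]
  expect_equal(nrow(recs), nrow(truth_after_sieve))

  # without the cleaning pass the reflections would be counted
  raw <- apply_sieve_filter(
    measure_areas(detect_particles(fix$image, mask), cal), 0.4
  )
  cleaned_small_sieve <- apply_sieve_filter(
    measure_areas(detect_particles(cleaned, mask), cal), 0.4
  )
  expect_gt(nrow(raw), nrow(cleaned_small_sieve))

  # a reflection-free image is returned unchanged
  clean_fix <- plate_fixture("clean")
  clean_mask <- isolate_plate(clean_fix$image)
  expect_identical(
    remove_reflections(clean_fix$image, clean_mask, cal,
                       brightness_min = 0.999, saturation_max = 0.001),
    clean_fix$image
  )

  # a white cotyledon particle above the size cut-off is never removed
  big_white <- truth_after_sieve[truth_after_sieve$class == "white" &
                                   truth_after_sieve$area_mm2 > 2, ]
  m <- match_truth(recs, fix$truth)
  expect_true(all(big_white$particle_id %in% fix$truth$particle_id[m]))
})

test_that("particle detection and measurement match the rendered ground truth", {
  fix <- plate_fixture("clean")
  cal <- fixture_calibration(fix)
  mask <- isolate_plate(fix$image)

  empty <- simulate_plate(plate_spec(n_white = 0, n_black = 0,
                                     image_size_px = 400, seed = 5))
  empty_regions <- detect_particles(empty$image, isolate_plate(empty$image))
  expect_equal(nrow(empty_regions), 0)

  regions <- detect_particles(fix$image, mask)
  recs <- apply_sieve_filter(measure_areas(regions, cal), 1)
  truth <- fix$truth[2 * sqrt(fix$truth$area_mm2 / pi) >= 1, ]
  expect_equal(nrow(recs), nrow(truth))

  m <- match_truth(recs, truth)
  expect_equal(sort(m), seq_len(nrow(truth)))  # one-to-one match
  rel_err <- abs(recs$area_mm2 - truth$area_mm2[m]) / truth$area_mm2[m]
  big <- truth$area_mm2[m] >= 2
  expect_lte(mean(rel_err[big]), 0.03)
})

test_that("colour classification separates seed coat from cotyledon", {
  fix <- plate_fixture("clean")
  cal <- fixture_calibration(fix)
  mask <- isolate_plate(fix$image)
  recs <- classify_particles(
    apply_sieve_filter(measure_areas(detect_particles(fix$image, mask), cal), 1)
  )
  truth <- fix$truth[2 * sqrt(fix$truth$area_mm2 / pi) >= 1, ]
  m <- match_truth(recs, truth)
  expect_equal(mean(recs$class == truth$class[m]), 1)

  # two particles, one near-black and one near-white
  two <- tibble::tibble(particle_id = 1:2, area_mm2 = c(3, 4),
                        mean_r = c(0.1, 0.9), mean_g = c(0.1, 0.9),
                        mean_b = c(0.1, 0.85))
  expect_equal(classify_particles(two)$class, c("black", "white"))

  # identical colours: single class with a warning, side chosen by luminance
  same <- tibble::tibble(particle_id = 1:3, mean_r = 0.9, mean_g = 0.9,
                         mean_b = 0.9)
  expect_warning(out <- classify_particles(same), "single class")
  expect_true(all(out$class == "white"))
  dark <- dplyr::mutate(same, mean_r = 0.1, mean_g = 0.1, mean_b = 0.1)
  expect_warning(out2 <- classify_particles(dark), "single class")
  expect_true(all(out2$class == "black"))
})

test_that("sieve filtering emulates the 1 mm preparation sieve", {
  recs <- tibble::tibble(particle_id = 1:3, area_mm2 = c(0.5, 5, pi / 4))
  kept <- apply_sieve_filter(recs, 1)
  expect_equal(kept$particle_id, c(2L, 3L))  # 0.5 mm^2 is d = 0.80 mm, removed
  expect_identical(apply_sieve_filter(recs, 0), recs)

  # monotone: raising the threshold never increases the retained count
  withr::with_seed(81, {
    areas <- tibble::tibble(particle_id = 1:50,
                            area_mm2 = sample_rosin_rammler(50, 4, 1.5))
  })
  counts <- vapply(seq(0, 4, by = 0.25),
                   function(th) nrow(apply_sieve_filter(areas, th)),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("multi-image bolus analysis pools records additively and deterministically", {
  fix <- plate_fixture("clean")
  refl <- plate_fixture("reflective")
  cal <- fixture_calibration(fix)

  single <- analyze_bolus(fix$image, cal)
  pooled <- analyze_bolus(list(fix$image, refl$image), cal)
  single2 <- analyze_bolus(refl$image, cal)
  expect_equal(nrow(pooled), nrow(single) + nrow(single2))
  expect_equal(pooled$particle_id, seq_len(nrow(pooled)))

  # pooled class counts agree with the pooled ground truth
  truth_counts <- table(c(
    fix$truth$class[2 * sqrt(fix$truth$area_mm2 / pi) >= 1],
    refl$truth$class[2 * sqrt(refl$truth$area_mm2 / pi) >= 1]
  ))
  got <- table(pooled$class)
  expect_equal(as.integer(got[names(truth_counts)]),
               as.integer(truth_counts))

  # determinism of the full pipeline
  expect_identical(analyze_bolus(fix$image, cal), single)

  # area conservation: total particle area cannot exceed the plate area
  mask <- isolate_plate(fix$image)
  expect_lte(sum(single$area_mm2), sum(mask) * cal$mm_per_px^2)

  expect_error(analyze_bolus(list(), cal), class = "beanbolus_parameter_error")
})
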