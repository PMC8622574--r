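#' Specification for a synthetic bolus plate image
#'
#' Describes the scene rendered by [simulate_plate()]: a blue circular plate
#' holding dispersed bolus particles of two colour classes (dark seed coat,
#' near-white cotyledon), an optional set of small specular reflections, and
#' a calibration bar of known physical length outside the plate.
#'
#' @param n_white,n_black Number of cotyledon ("white") and seed-coat
#'   ("black") particles.
#' @param rr_white,rr_black Rosin-Rammler parameters `c(x50, b)` (mm^2,
#'   dimensionless) from which each class's particle areas are drawn.
#'   Defaults reflect typical masticated-bean boluses, where seed-coat
#'   fragments are larger than cotyledon fragments.
#' @param plate_diameter_mm Plate diameter, mm (default 177).
#' @param background_colour RGB triple in `[0, 1]` for the plate background
#'   (default a saturated blue).
#' @param n_reflections Number of small bright low-saturation reflection
#'   blobs (each under 1 mm^2).
#' @param marker_length_mm Physical length of the calibration bar, mm.
#' @param image_size_px Output image is `image_size_px` x `image_size_px`.
#' @param pixel_noise_sd Per-pixel Gaussian colour noise.
#' @param seed Integer seed; rendering is bit-reproducible given the spec.
#' @return A `plate_spec` list.
#' @export
plate_spec <- function(n_white = 30, n_black = 15,
                       rr_white = c(x50 = 3.5, b = 1.9),
                       rr_black = c(x50 = 7.0, b = 1.7),
                       plate_diameter_mm = 177,
                       background_colour = c(0.10, 0.30, 0.75),
                       n_reflections = 0,
                       marker_length_mm = 20,
                       image_size_px = 900,
                       pixel_noise_sd = 0.008,
                       seed = 1) {
  check_positive_scalar(plate_diameter_mm, "plate_diameter_mm")
  check_positive_scalar(marker_length_mm, "marker_length_mm")
  check_positive_scalar(image_size_px, "image_size_px")
  for (p in list(rr_white, rr_black)) {
    check_positive_scalar(p[[1]], "x50")
    check_positive_scalar(p[[2]], "b")
  }
  if (n_white < 0 || n_black < 0 || n_reflections < 0) {
    bb_abort("Particle and reflection counts must be non-negative.",
             "beanbolus_parameter_error")
  }
  structure(
    list(
      n_white = n_white, n_black = n_black,
      rr_white = rr_white, rr_black = rr_black,
      plate_diameter_mm = plate_diameter_mm,
      background_colour = background_colour,
      n_reflections = n_reflections,
      marker_length_mm = marker_length_mm,
      image_size_px = as.integer(image_size_px),
      pixel_noise_sd = pixel_noise_sd,
      seed = seed
    ),
    class = "plate_spec"
  )
}

# Rasterise one perturbed ellipse as the round(target_px) pixels with the
# smallest normalised radial coordinate, so the rendered pixel count matches
# the requested area to within half a pixel regardless of quantisation.
rasterise_blob <- function(cx, cy, target_px, aspect, angle,
                           wobble_amp, wobble_k, wobble_phase, dim_px) {
  n_target <- max(round(target_px), 1L)
  a <- sqrt(target_px * aspect / pi)
  b <- a / aspect
  grow <- 1.4
  repeat {
    r_max <- max(a, b) * (1 + wobble_amp) * grow
    xs <- max(1L, floor(cx - r_max)):min(dim_px, ceiling(cx + r_max))
    ys <- max(1L, floor(cy - r_max)):min(dim_px, ceiling(cy + r_max))
    gx <- rep(xs, times = length(ys)) - cx
    gy <- rep(ys, each = length(xs)) - cy
    xr <- gx * cos(angle) + gy * sin(angle)
    yr <- -gx * sin(angle) + gy * cos(angle)
    rn <- sqrt((xr / a)^2 + (yr / b)^2)
    theta <- atan2(yr / b, xr / a)
    # normalised "depth" into the wobbled boundary; < 1 is inside the shape
    m <- rn / (1 + wobble_amp * sin(wobble_k * theta + wobble_phase))
    if (sum(is.finite(m)) >= n_target || grow > 4) break
    grow <- grow * 1.5
  }
  pick <- order(m)[seq_len(min(n_target, length(m)))]
  cbind(rep(xs, times = length(ys))[pick],
        rep(ys, each = length(xs))[pick])
}

#' Render a synthetic bolus plate image with ground truth
#'
#' Draws non-overlapping particles (perturbed ellipses with aspect ratio
#' drawn from U(1, 3) and sinusoidal boundary noise) on a blue plate disc,
#' plus an optional set of bright low-saturation reflection blobs and a
#' calibration bar outside the plate. Each blob is rasterised as exactly
#' `round(area / px_area)` pixels, so the rendered pixel area matches the
#' requested area to within half a pixel; the ground truth records the
#' rendered pixel count.
#'
#' @param spec A [plate_spec()].
#' @return A list of class `plate_render` with elements:
#'   * `image`: `H x W x 3` array in `[0, 1]`,
#'   * `truth`: tibble of per-particle ground truth (`particle_id`, `class`,
#'     `area_mm2`, `requested_area_mm2`, `centroid_x_px`, `centroid_y_px`,
#'     `pixel_count`),
#'   * `calibration`: tibble with `mm_per_px`, `marker_length_mm`,
#'     `marker_length_px`,
#'   * `plate`: list with the plate disc centre and radius in px.
#' @examples
#' render <- simulate_plate(plate_spec(n_white = 5, n_black = 3, seed = 2))
#' render$truth
#' @export
simulate_plate <- function(spec) {
  stopifnot(inherits(spec, "plate_spec"))
  dim_px <- spec$image_size_px
  scene_mm <- spec$plate_diameter_mm * 1.2
  mm_per_px <- scene_mm / dim_px
  px_area <- mm_per_px^2
  r_plate <- spec$plate_diameter_mm / 2 / mm_per_px
  centre <- (dim_px + 1) / 2

  with_local_seed(spec$seed, {
    n_w <- spec$n_white
    n_b <- spec$n_black
    areas <- c(
      if (n_w > 0) sample_rosin_rammler(n_w, spec$rr_white[[1]], spec$rr_white[[2]]) else numeric(0),
      if (n_b > 0) sample_rosin_rammler(n_b, spec$rr_black[[1]], spec$rr_black[[2]]) else numeric(0)
    )
    classes <- rep(c("white", "black"), times = c(n_w, n_b))
    plate_area_mm2 <- pi * (spec$plate_diameter_mm / 2)^2
    if (sum(areas) > 0.6 * plate_area_mm2) {
      bb_abort("Requested particle area exceeds 60% of the plate area; cannot pack.",
               "beanbolus_packing_error")
    }

    img <- array(0.22, dim = c(dim_px, dim_px, 3))    # neutral bench outside plate
    xg <- matrix(rep(seq_len(dim_px), each = dim_px), dim_px)   # column index
    yg <- matrix(rep(seq_len(dim_px), times = dim_px), dim_px)  # row index
    in_plate <- (xg - centre)^2 + (yg - centre)^2 <= r_plate^2
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[in_plate] <- spec$background_colour[ch]
      img[, , ch] <- plane
    }

    # place particles largest-first by rejection sampling on bounding circles
    ord <- order(areas, decreasing = TRUE)
    truth <- vector("list", length(areas))
    occupied_x <- numeric(0); occupied_y <- numeric(0); occupied_r <- numeric(0)
    for (i in ord) {
      target_px <- max(areas[i] / px_area, 1)
      aspect <- runif(1, 1, 3)
      angle <- runif(1, 0, 2 * pi)
      amp <- runif(1, 0.02, 0.08)
      k <- sample(3:7, 1)
      phase <- runif(1, 0, 2 * pi)
      r_bound <- sqrt(target_px * aspect / pi) * (1 + amp) + 2
      ok <- FALSE
      for (attempt in 1:2000) {
        rr <- sqrt(runif(1)) * max(r_plate - r_bound - 8, 1)
        th <- runif(1, 0, 2 * pi)
        cx <- centre + rr * cos(th)
        cy <- centre + rr * sin(th)
        if (length(occupied_r) == 0 ||
            all(sqrt((occupied_x - cx)^2 + (occupied_y - cy)^2) >
                occupied_r + r_bound + 3)) {
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        bb_abort("Could not place all particles without overlap; reduce counts or areas.",
                 "beanbolus_packing_error")
      }
      idx <- rasterise_blob(cx, cy, target_px, aspect, angle, amp, k, phase, dim_px)
      base <- if (classes[i] == "white") c(0.90, 0.86, 0.79) else c(0.13, 0.12, 0.11)
      jitter <- runif(3, -0.02, 0.02)
      lin <- (idx[, 1] - 1L) * dim_px + idx[, 2]       # [col, row] -> linear
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[lin] <- min(max(base[ch] + jitter[ch], 0), 1)
        img[, , ch] <- plane
      }
      occupied_x <- c(occupied_x, cx); occupied_y <- c(occupied_y, cy)
      occupied_r <- c(occupied_r, r_bound)
      truth[[i]] <- tibble::tibble(
        class = classes[i],
        requested_area_mm2 = areas[i],
        pixel_count = nrow(idx),
        area_mm2 = nrow(idx) * px_area,
        centroid_x_px = mean(idx[, 1]),
        centroid_y_px = mean(idx[, 2])
      )
    }

    # specular reflections: small bright low-saturation discs on the plate
    if (spec$n_reflections > 0) {
      for (j in seq_len(spec$n_reflections)) {
        refl_mm2 <- runif(1, 0.2, 0.9)
        target_px <- max(refl_mm2 / px_area, 1)
        r_bound <- sqrt(target_px / pi) + 2
        for (attempt in 1:2000) {
          rr <- sqrt(runif(1)) * (r_plate - r_bound - 8)
          th <- runif(1, 0, 2 * pi)
          cx <- centre + rr * cos(th)
          cy <- centre + rr * sin(th)
          if (length(occupied_r) == 0 ||
              all(sqrt((occupied_x - cx)^2 + (occupied_y - cy)^2) >
                  occupied_r + r_bound + 3)) break
        }
        idx <- rasterise_blob(cx, cy, target_px, 1, 0, 0, 3, 0, dim_px)
        lin <- (idx[, 1] - 1L) * dim_px + idx[, 2]
        for (ch in 1:3) {
          plane <- img[, , ch]
          plane[lin] <- 0.985
          img[, , ch] <- plane
        }
        occupied_x <- c(occupied_x, cx); occupied_y <- c(occupied_y, cy)
        occupied_r <- c(occupied_r, r_bound)
      }
    }

    # calibration bar: dark rectangle in the top-left corner, outside the plate
    marker_px <- spec$marker_length_mm / mm_per_px
    bar_rows <- 12:24
    bar_cols <- 12:(12 + round(marker_px) - 1)
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[bar_rows, bar_cols] <- 0.05
      img[, , ch] <- plane
    }

    if (spec$pixel_noise_sd > 0) {
      img <- img + array(rnorm(length(img), 0, spec$pixel_noise_sd), dim = dim(img))
      img[img < 0] <- 0
      img[img > 1] <- 1
    }

    truth_df <- dplyr::bind_rows(truth)
    if (nrow(truth_df) > 0) {
      truth_df <- tibble::add_column(truth_df,
                                     particle_id = seq_len(nrow(truth_df)),
                                     .before = 1)
    } else {
      truth_df <- tibble::tibble(
        particle_id = integer(), class = character(),
        requested_area_mm2 = numeric(), pixel_count = integer(),
        area_mm2 = numeric(), centroid_x_px = numeric(), centroid_y_px = numeric()
      )
    }
    structure(
      list(
        image = img,
        truth = truth_df,
        calibration = tibble::tibble(
          mm_per_px = mm_per_px,
          marker_length_mm = spec$marker_length_mm,
          marker_length_px = marker_px
        ),
        plate = list(centre_px = c(centre, centre), radius_px = r_plate)
      ),
      class = "plate_render"
    )
  })
}

#' Write a rendered plate to disk (PNG image, ground-truth and sidecar CSVs)
#'
#' @param render A `plate_render` from [simulate_plate()].
#' @param dir Output directory (created if needed).
#' @param stem File-name stem.
#' @return Invisibly, the paths written (`image`, `truth`, `calibration`).
#' @export
write_plate <- function(render, dir, stem = "plate") {
  stopifnot(inherits(render, "plate_render"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    image = file.path(dir, paste0(stem, ".png")),
    truth = file.path(dir, paste0(stem, "_truth.csv")),
    calibration = file.path(dir, paste0(stem, "_calibration.csv"))
  )
  png::writePNG(render$image, paths$image)
  utils::write.csv(render$truth, paths$truth, row.names = FALSE)
  utils::write.csv(render$calibration, paths$calibration, row.names = FALSE)
  invisible(paths)
}

#' Read a plate photograph from a PNG file
#'
#' @param path Path to an RGB PNG image.
#' @return An `H x W x 3` array in `[0, 1]`.
#' @export
read_plate_image <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), dim = c(dim(img), 3))
  img[, , 1:3, drop = FALSE]
}
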