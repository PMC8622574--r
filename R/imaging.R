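#' Spatial calibration from a reference marker
#'
#' Converts the measured pixel length of a geometrical reference of known
#' physical length into a scale factor.
#'
#' @param marker_length_mm Physical length of the marker, mm (> 0).
#' @param marker_length_px Measured length of the marker in the image, px (> 0).
#' @return A `bolus_calibration` object holding `mm_per_px`.
#' @examples
#' calibrate(10, 100)  # 0.1 mm/px
#' @export
calibrate <- function(marker_length_mm, marker_length_px) {
  check_positive_scalar(marker_length_mm, "marker_length_mm")
  check_positive_scalar(marker_length_px, "marker_length_px")
  structure(list(mm_per_px = marker_length_mm / marker_length_px),
            class = "bolus_calibration")
}

as_mm_per_px <- function(calibration) {
  if (inherits(calibration, "bolus_calibration")) return(calibration$mm_per_px)
  if (is.data.frame(calibration) && "mm_per_px" %in% names(calibration)) {
    return(calibration$mm_per_px[1])
  }
  if (is.numeric(calibration) && length(calibration) == 1L && calibration > 0) {
    return(as.numeric(calibration))
  }
  bb_abort("A calibration (mm per pixel) is required; see `calibrate()`.",
           "beanbolus_calibration_error")
}

# hue (degrees), saturation, value planes from an RGB array
image_hsv <- function(image) {
  stopifnot(length(dim(image)) == 3L, dim(image)[3] >= 3L)
  d <- dim(image)[1:2]
  rgb <- rbind(as.vector(image[, , 1]), as.vector(image[, , 2]),
               as.vector(image[, , 3]))
  hsv <- grDevices::rgb2hsv(rgb, maxColorValue = 1)
  list(
    h = matrix(hsv[1, ] * 360, d[1], d[2]),
    s = matrix(hsv[2, ], d[1], d[2]),
    v = matrix(hsv[3, ], d[1], d[2])
  )
}

largest_component <- function(mask) {
  lab <- EBImage::bwlabel(mask * 1)
  if (max(lab) == 0) return(NULL)
  counts <- tabulate(lab[lab > 0])
  lab == which.max(counts)
}

#' Isolate the plate region by colour thresholding
#'
#' Thresholds the image in HSV space around the plate's background hue, keeps
#' the largest connected component and fills its holes (the particles sitting
#' on the plate), yielding a mask of the full plate disc.
#'
#' @param image `H x W x 3` RGB array in `[0, 1]`.
#' @param target_hue Plate hue in degrees (default 220, blue).
#' @param hue_window Full width of the accepted hue window, degrees.
#' @param min_saturation,min_value Lower HSV bounds for plate pixels.
#' @param min_fraction Minimum fraction of the frame the plate must cover;
#'   below this a "plate not found" error is raised.
#' @return Logical matrix: the plate mask.
#' @export
isolate_plate <- function(image, target_hue = 220, hue_window = 60,
                          min_saturation = 0.25, min_value = 0.15,
                          min_fraction = 0.1) {
  hsv <- image_hsv(image)
  dh <- abs(hsv$h - target_hue)
  dh <- pmin(dh, 360 - dh)
  cand <- dh <= hue_window / 2 & hsv$s >= min_saturation & hsv$v >= min_value
  comp <- largest_component(cand)
  if (is.null(comp) || mean(comp) < min_fraction) {
    bb_abort("Plate not found: no sufficiently large region matches the plate colour.",
             "beanbolus_plate_error")
  }
  EBImage::fillHull(comp) > 0
}

#' Remove specular reflections from the plate
#'
#' Connected regions inside the plate that are simultaneously bright, of low
#' colour saturation and smaller than `max_area_mm2` are treated as light
#' reflections and painted over with the plate's background colour, so they
#' cannot be picked up as particles downstream. Pixels not matching all three
#' conditions are left untouched; with no matching region the image is
#' returned unchanged.
#'
#' @param image RGB array.
#' @param plate_mask Logical plate mask from [isolate_plate()].
#' @param calibration Calibration (see [calibrate()]); needed to express the
#'   size cut-off in mm^2.
#' @param brightness_min Minimum HSV value for a reflection pixel.
#' @param saturation_max Maximum HSV saturation for a reflection pixel.
#' @param max_area_mm2 Regions at or above this area are never removed.
#' @return The cleaned RGB array.
#' @export
remove_reflections <- function(image, plate_mask, calibration,
                               brightness_min = 0.95, saturation_max = 0.06,
                               max_area_mm2 = 1) {
  mm_per_px <- as_mm_per_px(calibration)
  hsv <- image_hsv(image)
  cand <- plate_mask & hsv$v >= brightness_min & hsv$s <= saturation_max
  if (!any(cand)) return(image)
  lab <- EBImage::bwlabel(cand * 1)
  counts <- tabulate(lab[lab > 0])
  small <- which(counts * mm_per_px^2 < max_area_mm2)
  if (length(small) == 0) return(image)
  kill <- lab %in% small & lab > 0
  bg <- vapply(1:3, function(ch) {
    plane <- image[, , ch]
    median(plane[plate_mask & !cand])
  }, numeric(1))
  for (ch in 1:3) {
    plane <- image[, , ch]
    plane[kill] <- bg[ch]
    image[, , ch] <- plane
  }
  image
}

#' Detect particles on the plate
#'
#' Flags every plate pixel whose colour departs from the plate background by
#' more than `colour_threshold` (Euclidean RGB distance), fills holes, and
#' labels connected components. Regions touching the plate boundary are kept
#' but flagged. An optional Gaussian blur suppresses pixel noise before
#' thresholding.
#'
#' @param image RGB array (ideally cleaned by [remove_reflections()]).
#' @param plate_mask Logical plate mask.
#' @param colour_threshold RGB distance above which a pixel is foreground.
#' @param blur_sigma Gaussian blur radius in px (0 disables blurring).
#' @param min_pixels Discard regions smaller than this many pixels.
#' @return A tibble of labelled regions: `particle_id`, `pixel_count`,
#'   `centroid_x_px`, `centroid_y_px`, `mean_r`, `mean_g`, `mean_b`,
#'   `boundary_flag`. The label matrix is attached as attribute `"labels"`.
#' @export
detect_particles <- function(image, plate_mask, colour_threshold = 0.25,
                             blur_sigma = 0, min_pixels = 4) {
  if (blur_sigma > 0) {
    for (ch in 1:3) image[, , ch] <- EBImage::gblur(image[, , ch], sigma = blur_sigma)
  }
  bg <- vapply(1:3, function(ch) median(image[, , ch][plate_mask]), numeric(1))
  dist2 <- (image[, , 1] - bg[1])^2 + (image[, , 2] - bg[2])^2 +
    (image[, , 3] - bg[3])^2
  fg <- plate_mask & dist2 > colour_threshold^2
  fg <- EBImage::fillHull(EBImage::bwlabel(fg * 1)) > 0
  lab <- EBImage::bwlabel(fg * 1)
  n <- max(lab)
  empty <- tibble::tibble(
    particle_id = integer(), pixel_count = integer(),
    centroid_x_px = numeric(), centroid_y_px = numeric(),
    mean_r = numeric(), mean_g = numeric(), mean_b = numeric(),
    boundary_flag = logical()
  )
  if (n == 0) return(structure(empty, labels = lab))

  # plate-boundary pixels: plate pixels 4-adjacent to non-plate pixels
  pm <- plate_mask
  inner <- pm
  inner[-1, ] <- inner[-1, ] & pm[-nrow(pm), ]
  inner[-nrow(pm), ] <- inner[-nrow(pm), ] & pm[-1, ]
  inner[, -1] <- inner[, -1] & pm[, -ncol(pm)]
  inner[, -ncol(pm)] <- inner[, -ncol(pm)] & pm[, -1]
  border <- pm & !inner

  keep <- lab > 0
  labv <- lab[keep]
  rows <- row(lab)[keep]
  cols <- col(lab)[keep]
  px <- tabulate(labv, nbins = n)
  out <- tibble::tibble(
    particle_id = seq_len(n),
    pixel_count = px,
    centroid_x_px = as.numeric(tapply(cols, labv, mean)),
    centroid_y_px = as.numeric(tapply(rows, labv, mean)),
    mean_r = as.numeric(tapply(image[, , 1][keep], labv, mean)),
    mean_g = as.numeric(tapply(image[, , 2][keep], labv, mean)),
    mean_b = as.numeric(tapply(image[, , 3][keep], labv, mean)),
    boundary_flag = as.logical(tapply(border[keep], labv, any))
  )
  out <- out[out$pixel_count >= min_pixels, , drop = FALSE]
  out$particle_id <- seq_len(nrow(out))
  structure(out, labels = lab)
}

#' Convert region pixel counts to physical areas
#'
#' @param regions Region tibble from [detect_particles()].
#' @param calibration Calibration (see [calibrate()]).
#' @return The region tibble with an `area_mm2` column
#'   (`pixel_count * mm_per_px^2`), zero-pixel regions dropped, sorted by
#'   `particle_id`.
#' @export
measure_areas <- function(regions, calibration) {
  mm_per_px <- as_mm_per_px(calibration)
  regions <- regions[regions$pixel_count > 0, , drop = FALSE]
  regions$area_mm2 <- regions$pixel_count * mm_per_px^2
  dplyr::arrange(tibble::as_tibble(regions), .data$particle_id)
}

#' Classify particles into seed coat ("black") and cotyledon ("white")
#'
#' Two-class k-means on per-particle mean RGB colour. Initial centres are the
#' colours of the darkest and brightest particles (by luminance), which makes
#' the clustering deterministic. The cluster with the lower mean luminance is
#' labelled `"black"` (seed coat), the other `"white"` (cotyledon). With
#' fewer than two particles, or when all particles share one colour, a single
#' class is assigned with a warning: `"white"` if the common luminance is
#' above mid-grey, else `"black"`.
#'
#' @param records Particle tibble with `mean_r`, `mean_g`, `mean_b`.
#' @return The tibble with a `class` column added.
#' @export
classify_particles <- function(records) {
  stopifnot(all(c("mean_r", "mean_g", "mean_b") %in% names(records)))
  n <- nrow(records)
  if (n == 0) {
    records$class <- character(0)
    return(records)
  }
  lum <- luminance(records$mean_r, records$mean_g, records$mean_b)
  feats <- cbind(records$mean_r, records$mean_g, records$mean_b)
  if (n < 2 || max(lum) - min(lum) < 1e-6) {
    rlang::warn("Fewer than two distinct particle colours; assigning a single class.")
    records$class <- if (mean(lum) > 0.5) "white" else "black"
    return(records)
  }
  if (n == 2) {               # k-means with k = n is degenerate; label directly
    records$class <- ifelse(lum == min(lum), "black", "white")
    return(records)
  }
  centres <- feats[c(which.min(lum), which.max(lum)), , drop = FALSE]
  km <- stats::kmeans(feats, centers = centres)
  centre_lum <- luminance(km$centers[, 1], km$centers[, 2], km$centers[, 3])
  labels <- c("black", "white")[order(order(centre_lum))]
  records$class <- labels[km$cluster]
  records
}

#' Emulate the 1 mm preparation sieve in image space
#'
#' Retains particles whose equivalent circular diameter `2 sqrt(A / pi)` is
#' at least `min_equivalent_diameter_mm`. The physical preparation step
#' washes boluses on a 1 mm sieve, so image-detected fragments below that
#' size cannot correspond to retained material.
#'
#' @param records Particle tibble with `area_mm2`.
#' @param min_equivalent_diameter_mm Diameter threshold, mm (default 1).
#' @return The filtered tibble.
#' @export
apply_sieve_filter <- function(records, min_equivalent_diameter_mm = 1) {
  check_positive_scalar(min_equivalent_diameter_mm, "min_equivalent_diameter_mm",
                        strict = FALSE)
  if (min_equivalent_diameter_mm == 0) return(records)
  diam <- 2 * sqrt(records$area_mm2 / pi)
  records[diam >= min_equivalent_diameter_mm, , drop = FALSE]
}

#' Run the full segmentation pipeline on one or more plate images
#'
#' For each image: plate isolation, reflection removal, particle detection,
#' area measurement and sieve filtering; records are then pooled across
#' images (a bolus is typically photographed on four to ten plates), re-keyed
#' with unique particle ids, and classified into seed coat and cotyledon in a
#' single pass so the colour clustering sees the whole bolus.
#'
#' @param images A single RGB array or a list of them.
#' @param calibration Calibration shared by all images (see [calibrate()]).
#' @param min_equivalent_diameter_mm Sieve threshold passed to
#'   [apply_sieve_filter()].
#' @param source_ids Optional character ids for the images.
#' @param ... Further arguments passed to [isolate_plate()],
#'   [remove_reflections()] and [detect_particles()] via their defaults:
#'   `target_hue`, `hue_window`, `min_fraction`, `brightness_min`,
#'   `saturation_max`, `max_area_mm2`, `colour_threshold`, `blur_sigma`,
#'   `min_pixels`.
#' @return A tibble of classified particle records (`particle_id`,
#'   `source_id`, `class`, `pixel_count`, `area_mm2`, `mean_r`, `mean_g`,
#'   `mean_b`, `centroid_x_px`, `centroid_y_px`, `boundary_flag`).
#' @export
analyze_bolus <- function(images, calibration, min_equivalent_diameter_mm = 1,
                          source_ids = NULL, ...) {
  if (is.array(images)) images <- list(images)
  if (length(images) == 0) {
    bb_abort("At least one image is required.", "beanbolus_parameter_error")
  }
  dots <- list(...)
  pick <- function(f, names) dots[intersect(names, names(dots))]
  source_ids <- source_ids %||% sprintf("image%02d", seq_along(images))
  per_image <- purrr::map2(images, source_ids, function(img, sid) {
    mask <- do.call(isolate_plate,
                    c(list(image = img),
                      pick(isolate_plate, c("target_hue", "hue_window",
                                            "min_saturation", "min_value",
                                            "min_fraction"))))
    img <- do.call(remove_reflections,
                   c(list(image = img, plate_mask = mask, calibration = calibration),
                     pick(remove_reflections, c("brightness_min", "saturation_max",
                                                "max_area_mm2"))))
    regions <- do.call(detect_particles,
                       c(list(image = img, plate_mask = mask),
                         pick(detect_particles, c("colour_threshold", "blur_sigma",
                                                  "min_pixels"))))
    regions <- measure_areas(regions, calibration)
    regions <- apply_sieve_filter(regions, min_equivalent_diameter_mm)
    regions$source_id <- sid
    regions
  })
  pooled <- dplyr::bind_rows(per_image)
  if (nrow(pooled) == 0) {
    pooled$class <- character(0)
    return(tibble::as_tibble(pooled))
  }
  pooled$particle_id <- seq_len(nrow(pooled))
  pooled <- classify_particles(pooled)
  dplyr::select(pooled, "particle_id", "source_id", "class", "pixel_count",
                "area_mm2", dplyr::everything())
}
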