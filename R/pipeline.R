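#' Default configuration for an end-to-end synthetic run
#'
#' @param out_dir Directory where stage outputs (CSV) are persisted; `NULL`
#'   keeps everything in memory.
#' @param seed Master seed; per-stage seeds are derived from it.
#' @return A nested configuration list (also what `run_pipeline()` accepts
#'   from a YAML file with the same structure).
#' @export
default_pipeline_config <- function(out_dir = NULL, seed = 1) {
  list(
    out_dir = out_dir,
    seed = seed,
    panel = list(n_fast = 9, n_slow = 6, n_inconsistent = 2, target_r = 0.88),
    imaging = list(
      sample = "A",             # which sample's boluses get plate imaging
      images_per_bolus = 1,
      n_white = 20, n_black = 10,
      image_size_px = 700,
      sieve_mm = 1
    ),
    kinetics = list(
      total_starch_mg = 500,
      noise_sd_mg = 4,
      # generator link between chewing duration and digestion parameters:
      # longer chewing -> more released glucose and faster protein digestion
      s0_range = c(60, 160), sf_range = c(150, 330),
      ks_range = c(0.014, 0.025), kp_range = c(0.05, 0.12),
      duration_range_s = c(12, 78)
    )
  )
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    bb_abort(sprintf("Pipeline stage '%s' failed: %s", name, conditionMessage(e)),
             "beanbolus_pipeline_error")
  })
}

persist <- function(x, out_dir, file) {
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(x, file.path(out_dir, file), row.names = FALSE)
  }
  invisible(x)
}

# map a value linearly from one range onto another
rescale_range <- function(x, from, to) {
  to[1] + (x - from[1]) / (from[2] - from[1]) * (to[2] - to[1])
}

#' Run the full synthetic analysis pipeline
#'
#' Orchestrates simulate -> segment -> fit-PSD -> fit-kinetics -> classify ->
#' correlate from a single configuration: generates a chewer panel, renders
#' and segments plate images for each participant's bolus, fits
#' Rosin-Rammler distributions per colour class, simulates and fits starch
#' and protein digestion curves whose generator parameters are linked to
#' chewing duration, computes starch fractions, classifies chewers and
#' reports cross-metric correlations. Every intermediate table is persisted
#' as CSV when `out_dir` is set, and the run is deterministic for a fixed
#' configuration.
#'
#' @param config A configuration list (see [default_pipeline_config()]) or
#'   the path to a YAML file with the same structure.
#' @param quiet Suppress per-stage progress messages?
#' @return A `bolus_pipeline_report` list with tibbles `panel`, `particles`,
#'   `psd_fits`, `kinetics` (including the starch fractions), `labels`, and
#'   the correlation matrix `correlations`.
#' @examples
#' \donttest{
#' report <- run_pipeline(default_pipeline_config(seed = 7))
#' report$labels
#' }
#' @export
run_pipeline <- function(config = default_pipeline_config(), quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(default_pipeline_config(), config)
  say <- function(...) if (!quiet) message(sprintf(...))
  out <- cfg$out_dir

  say("stage panel: simulating %d participants",
      cfg$panel$n_fast + cfg$panel$n_slow + cfg$panel$n_inconsistent)
  panel <- pipeline_stage("panel", do.call(
    simulate_panel, c(cfg$panel, list(seed = cfg$seed))
  ))
  persist(panel, out, "panel.csv")
  participants <- unique(panel$participant_id)

  say("stage segment: rendering and segmenting %d plates", length(participants))
  im <- cfg$imaging
  particles <- pipeline_stage("segment", purrr::map_dfr(
    seq_along(participants), function(i) {
      imgs <- lapply(seq_len(im$images_per_bolus), function(k) {
        simulate_plate(plate_spec(
          n_white = im$n_white, n_black = im$n_black,
          image_size_px = im$image_size_px,
          seed = cfg$seed + 1000 + i * 100 + k
        ))
      })
      cal <- calibrate(imgs[[1]]$calibration$marker_length_mm,
                       imgs[[1]]$calibration$marker_length_px)
      recs <- analyze_bolus(lapply(imgs, `[[`, "image"), cal,
                            min_equivalent_diameter_mm = im$sieve_mm)
      recs$bolus_id <- participants[i]
      recs
    }
  ))
  persist(particles, out, "particles.csv")

  say("stage fit-psd: fitting Rosin-Rammler distributions")
  psd_fits <- pipeline_stage("fit-psd", fit_psd(particles, by_class = TRUE))
  persist(psd_fits, out, "psd_fits.csv")

  say("stage fit-kinetics: simulating and fitting digestion curves")
  kin <- cfg$kinetics
  per_part <- panel |>
    dplyr::summarise(duration_s = mean(.data$duration_s),
                     amylase = .data$amylase_cu_per_ml[1],
                     .by = "participant_id")
  kinetics <- pipeline_stage("fit-kinetics", purrr::map_dfr(
    seq_len(nrow(per_part)), function(i) {
      d <- per_part$duration_s[i]
      dr <- kin$duration_range_s
      s0 <- rescale_range(d, dr, kin$s0_range)
      sf <- rescale_range(d, dr, kin$sf_range)
      ks <- rescale_range(d, dr, kin$ks_range)
      kp <- rescale_range(d, dr, kin$kp_range)
      starch <- simulate_digesta("fractional_conversion",
                                 params = list(s0 = s0, sf = sf, ks = ks),
                                 noise_sd = kin$noise_sd_mg,
                                 seed = cfg$seed + 2000 + i)
      protein <- simulate_digesta("zero_order",
                                  params = list(p0 = 20, kp = kp),
                                  noise_sd = kin$noise_sd_mg,
                                  seed = cfg$seed + 3000 + i)
      sf_fit <- glance(fit_fractional_conversion(starch))
      pf_fit <- glance(fit_zero_order(protein))
      g <- function(t) starch$value_mg[starch$time_min == t]
      fr <- starch_fractions(g20 = max(g(20), 0),
                             g120 = max(g(120), g(20), 0),
                             total_starch = kin$total_starch_mg)
      tibble::tibble(
        participant_id = per_part$participant_id[i],
        s0 = sf_fit$s0, sf = sf_fit$sf, ks = sf_fit$ks,
        starch_adj_r2 = sf_fit$adj_r2,
        p0 = pf_fit$p0, kp = pf_fit$kp, protein_adj_r2 = pf_fit$adj_r2,
        rds = fr$rds, sds = fr$sds, rs = fr$rs
      )
    }
  ))
  persist(kinetics, out, "kinetics.csv")

  say("stage cohort: classifying chewers and correlating metrics")
  labels <- pipeline_stage("cohort", classify_chewers(panel))
  persist(labels, out, "labels.csv")

  metrics <- per_part |>
    dplyr::left_join(
      psd_fits |>
        dplyr::filter(.data$class_scope == "all") |>
        dplyr::select(participant_id = "bolus_id", x50 = "x50_mm2", "b"),
      by = "participant_id"
    ) |>
    dplyr::left_join(kinetics, by = "participant_id")
  correlations <- pipeline_stage("cohort", correlation_report(
    metrics, metrics = c("duration_s", "amylase", "x50", "b",
                         "ks", "kp", "rds", "sds", "rs")
  ))
  persist(as.data.frame(correlations), out, "correlations.csv")

  report <- structure(
    list(panel = panel, particles = particles, psd_fits = psd_fits,
         kinetics = kinetics, labels = labels, correlations = correlations,
         config = cfg),
    class = "bolus_pipeline_report"
  )
  say("pipeline complete: %d participants, %d particles",
      length(participants), nrow(particles))
  report
}

#' @export
print.bolus_pipeline_report <- function(x, ...) {
  cat("Bolus analysis pipeline report\n")
  cat(sprintf("  participants : %d\n", length(unique(x$panel$participant_id))))
  cat(sprintf("  particles    : %d segmented\n", nrow(x$particles)))
  cat(sprintf("  chewer classes: %s\n",
              paste(sprintf("%s=%d", names(table(x$labels$class)),
                            table(x$labels$class)), collapse = ", ")))
  cat(sprintf("  duration~amylase r = %.3f\n",
              x$correlations["duration_s", "amylase"]))
  invisible(x)
}
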