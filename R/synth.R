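#' Sample particle areas from a Rosin-Rammler distribution
#'
#' Draws areas by inverse-CDF sampling: with `u ~ Uniform(0, 1)`,
#' `x = x50 * (-log(1 - u) / log(2))^(1/b)`. Used by the plate simulator to
#' give synthetic boluses the size structure assumed by the analysis.
#'
#' @param n Number of particles to draw (>= 1).
#' @param x50 Median particle area, mm^2 (> 0).
#' @param b Breadth constant (> 0).
#' @param seed Optional integer seed; the caller's RNG state is untouched.
#' @return Numeric vector of `n` areas (mm^2).
#' @examples
#' sample_rosin_rammler(5, x50 = 5, b = 1.6, seed = 1)
#' @export
sample_rosin_rammler <- function(n, x50, b, seed = NULL) {
  check_positive_scalar(n, "n")
  check_positive_scalar(x50, "x50")
  check_positive_scalar(b, "b")
  with_local_seed(seed, {
    u <- runif(n)
    rr_quantile(u, x50, b)
  })
}

#' Simulate an in vitro digestion time course
#'
#' Generates analyte masses over digestion time from either the fractional
#' conversion model `S(t) = Sf + (S0 - Sf) exp(-ks t)` (starch, D-glucose) or
#' the zero-order model `P(t) = P0 + kp t` (protein, L-serine equivalents),
#' with additive homoscedastic Gaussian noise.
#'
#' @param model `"fractional_conversion"` or `"zero_order"`.
#' @param params Named list of model parameters: `s0`, `sf`, `ks` (min^-1)
#'   for fractional conversion; `p0`, `kp` (mg/min) for zero order. Masses in mg.
#' @param timepoints Sampling times in minutes, non-negative and strictly
#'   increasing. Defaults to the nine intestinal-phase sampling times used in
#'   the digestion assay.
#' @param noise_sd Standard deviation of additive Gaussian noise, mg (>= 0).
#' @param phase Digestion phase label stored in the output.
#' @param analyte Analyte label; defaults to the model's natural analyte.
#' @param seed Optional integer seed.
#' @return A tibble with columns `time_min`, `phase`, `analyte`, `value_mg`.
#' @examples
#' simulate_digesta("fractional_conversion",
#'                  params = list(s0 = 78.4, sf = 196.4, ks = 0.027))
#' @export
simulate_digesta <- function(model = c("fractional_conversion", "zero_order"),
                             params,
                             timepoints = c(0, 20, 30, 40, 60, 90, 120, 180, 240),
                             noise_sd = 0,
                             phase = "intestinal",
                             analyte = NULL,
                             seed = NULL) {
  model <- match.arg(model)
  check_positive_scalar(noise_sd, "noise_sd", strict = FALSE)
  if (any(timepoints < 0) || any(diff(timepoints) <= 0)) {
    bb_abort("`timepoints` must be non-negative and strictly increasing.",
             "beanbolus_parameter_error")
  }
  mean_value <- if (model == "fractional_conversion") {
    analyte <- analyte %||% "glucose"
    fractional_conversion(timepoints, params$s0, params$sf, params$ks)
  } else {
    analyte <- analyte %||% "serine"
    check_positive_scalar(params$p0, "p0", strict = FALSE)
    params$p0 + params$kp * timepoints
  }
  value <- with_local_seed(seed, mean_value + rnorm(length(timepoints), 0, noise_sd))
  tibble::tibble(
    time_min = as.numeric(timepoints),
    phase = phase,
    analyte = analyte,
    value_mg = value
  )
}

#' Simulate a chewing panel with fast, slow and inconsistent chewers
#'
#' Builds a participant table with three per-sample chewing durations placed
#' relative to per-sample reference medians: fast chewers sit strictly below
#' every reference, slow chewers strictly above, and inconsistent chewers are
#' mixed. For each sample an inconsistent chewer designated "fast-side" is
#' placed exactly at the fastest-chewer boundary for that sample, so the
#' cohort median of the generated durations lands on the boundary between the
#' fast group and everyone else — mirroring a real panel where the median
#' participant chews exactly at the median line. Salivary alpha-amylase
#' activity is generated as a linear function of a participant's mean chewing
#' duration plus Gaussian noise calibrated so that the panel-level Pearson
#' correlation between duration and amylase approximates `target_r`.
#'
#' @param n_fast,n_slow,n_inconsistent Group sizes (default 9/6/2, the
#'   composition observed in a 17-person mastication panel).
#' @param median_anchor_s Named per-sample reference medians in seconds
#'   (defaults 28.5, 29 and 24.75 s for samples A, B and C).
#' @param fast_range_s,slow_range_s Duration ranges (s) for the fast and slow
#'   groups; fast draws are truncated below the per-sample anchor, slow draws
#'   above it.
#' @param target_r Target Pearson correlation between mean chewing duration
#'   and amylase activity (|r| <= 1; default 0.88).
#' @param amylase_slope Amylase activity per second of chewing
#'   (CU mL^-1 s^-1).
#' @param amylase_intercept Baseline amylase activity (CU/mL).
#' @param resolution_s Timer resolution used to round durations (s).
#' @param seed Optional integer seed.
#' @return A tibble with one row per participant and sample: `participant_id`,
#'   `sample`, `duration_s`, `amylase_cu_per_ml`, `designed_class`.
#' @examples
#' panel <- simulate_panel(seed = 1)
#' dplyr::count(panel, designed_class) # 3 samples per participant
#' @export
simulate_panel <- function(n_fast = 9, n_slow = 6, n_inconsistent = 2,
                           median_anchor_s = c(A = 28.5, B = 29, C = 24.75),
                           fast_range_s = c(12, 24),
                           slow_range_s = c(30, 78),
                           target_r = 0.88,
                           amylase_slope = 0.004,
                           amylase_intercept = 0.02,
                           resolution_s = 0.25,
                           seed = NULL) {
  for (nm in c("n_fast", "n_slow", "n_inconsistent")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v < 0 || v != round(v)) {
      bb_abort(sprintf("`%s` must be a non-negative integer count.", nm),
               "beanbolus_parameter_error")
    }
  }
  if (abs(target_r) > 1) {
    bb_abort("`target_r` must lie in [-1, 1].", "beanbolus_parameter_error")
  }
  samples <- names(median_anchor_s)
  if (is.null(samples)) samples <- LETTERS[seq_along(median_anchor_s)]
  n_samples <- length(samples)
  if (n_inconsistent > 0 && n_samples < 2) {
    bb_abort("Inconsistent chewers need at least 2 samples to be mixed across.",
             "beanbolus_spec_error")
  }
  if (any(fast_range_s <= 0) || any(slow_range_s <= 0)) {
    bb_abort("Duration ranges must be positive.", "beanbolus_parameter_error")
  }
  n <- n_fast + n_slow + n_inconsistent
  with_local_seed(seed, {
    groups <- rep(c("fast", "slow", "inconsistent"),
                  times = c(n_fast, n_slow, n_inconsistent))
    dur <- matrix(NA_real_, nrow = n, ncol = n_samples,
                  dimnames = list(NULL, samples))
    snap <- function(x) round(x / resolution_s) * resolution_s
    for (j in seq_len(n_samples)) {
      m <- median_anchor_s[j]
      hi_fast <- min(fast_range_s[2], m - resolution_s)
      lo_slow <- max(slow_range_s[1], m + resolution_s)
      if (n_fast > 0) {
        dur[groups == "fast", j] <- snap(runif(n_fast, fast_range_s[1], hi_fast))
      }
      if (n_slow > 0) {
        dur[groups == "slow", j] <- snap(runif(n_slow, lo_slow, slow_range_s[2]))
      }
    }
    # Inconsistent chewer k chews slowly on sample 1 + (k-1) mod n_samples and
    # at the fast boundary elsewhere; the shared boundary value makes the
    # cohort median fall exactly between the fast group and the rest.
    idx_inc <- which(groups == "inconsistent")
    for (k in seq_along(idx_inc)) {
      slow_sample <- 1L + (k - 1L) %% n_samples
      for (j in seq_len(n_samples)) {
        m <- median_anchor_s[j]
        if (j == slow_sample) {
          dur[idx_inc[k], j] <- snap(runif(1, max(slow_range_s[1], m + resolution_s),
                                           slow_range_s[2]))
        } else {
          boundary <- if (n_fast > 0) max(dur[groups == "fast", j]) else m - resolution_s
          dur[idx_inc[k], j] <- boundary
        }
      }
    }
    mean_dur <- rowMeans(dur)
    sgn <- if (target_r >= 0) 1 else -1
    signal <- amylase_intercept + sgn * amylase_slope * mean_dur
    amylase <- if (abs(target_r) %in% c(0, 1) || n < 3 || sd(mean_dur) == 0) {
      if (target_r == 0) amylase_intercept + rnorm(n, 0, amylase_slope * 10) else signal
    } else {
      noise_sd <- amylase_slope * sd(mean_dur) * sqrt(1 / target_r^2 - 1)
      signal + rnorm(n, 0, noise_sd)
    }
    tibble::tibble(
      participant_id = rep(sprintf("P%02d", seq_len(n)), each = n_samples),
      sample = rep(samples, times = n),
      duration_s = as.vector(t(dur)),
      amylase_cu_per_ml = rep(amylase, each = n_samples),
      designed_class = rep(groups, each = n_samples)
    )
  })
}

#' Simulate a double-compression texture profile analysis force curve
#'
#' Builds a two-bite force-time curve from target texture parameters. Each
#' compression cycle is a pair of quarter-sine segments: a compression stroke
#' rising to the cycle peak and a withdrawal stroke returning to zero. The
#' second cycle's peak and durations are chosen so that the curve reproduces
#' the requested cohesiveness (cycle-2/cycle-1 area ratio), springiness
#' (compression-duration ratio) and resilience (withdrawal/compression area
#' ratio within cycle 1).
#'
#' @param hardness Peak force of the first compression, N.
#' @param cohesiveness Target area ratio of cycle 2 to cycle 1 (> 0).
#' @param springiness Target compression-duration ratio (> 0).
#' @param resilience Target withdrawal/compression area ratio of cycle 1.
#' @param compression_s Duration of the first compression stroke, s.
#' @param gap_s Rest time between the two cycles, s.
#' @param dt Sampling interval, s.
#' @param noise_sd Additive force noise, N.
#' @param seed Optional integer seed.
#' @return A tibble with columns `time_s` and `force_n`.
#' @examples
#' curve <- simulate_tpa_curve(hardness = 10, cohesiveness = 0.5,
#'                             springiness = 0.8)
#' compute_tpa(curve)
#' @export
simulate_tpa_curve <- function(hardness = 10, cohesiveness = 0.5,
                               springiness = 0.8, resilience = 1,
                               compression_s = 1, gap_s = 0.5,
                               dt = 0.002, noise_sd = 0, seed = NULL) {
  check_positive_scalar(hardness, "hardness")
  check_positive_scalar(cohesiveness, "cohesiveness")
  check_positive_scalar(springiness, "springiness")
  check_positive_scalar(resilience, "resilience")
  check_positive_scalar(compression_s, "compression_s")
  check_positive_scalar(noise_sd, "noise_sd", strict = FALSE)

  cycle <- function(peak, comp, withd) {
    t_up <- seq(0, comp, by = dt)
    t_down <- seq(dt, withd, by = dt)
    f <- c(peak * sin(pi * t_up / (2 * comp)),
           peak * cos(pi * t_down / (2 * withd)))
    list(t = c(t_up, comp + t_down), f = pmax(f, 0))
  }
  c1 <- compression_s
  w1 <- resilience * c1
  c2 <- springiness * c1
  w2 <- resilience * c2
  # quarter-sine areas are (2/pi) * peak * duration, so the area ratio is
  # peak2 (c2 + w2) / (peak1 (c1 + w1))
  peak2 <- cohesiveness * hardness * (c1 + w1) / (c2 + w2)

  cyc1 <- cycle(hardness, c1, w1)
  cyc2 <- cycle(peak2, c2, w2)
  lead <- seq(0, 0.1, by = dt)
  t <- c(lead,
         0.1 + dt + cyc1$t,
         0.1 + dt + max(cyc1$t) + seq(dt, gap_s, by = dt),
         0.1 + 2 * dt + max(cyc1$t) + gap_s + cyc2$t)
  f <- c(rep(0, length(lead)), cyc1$f,
         rep(0, length(seq(dt, gap_s, by = dt))), cyc2$f)
  f <- with_local_seed(seed, pmax(f + rnorm(length(f), 0, noise_sd), 0))
  tibble::tibble(time_s = t, force_n = f)
}
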