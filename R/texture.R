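#' Specific energy input of a pulsed electric field treatment
#'
#' Energy delivered per unit mass of product plus conducting medium:
#' `pulse_energy * pulse_count / total_mass`, reported in kJ/kg.
#'
#' @param pulse_energy_j Energy per pulse, J.
#' @param pulse_count Number of pulses (>= 0).
#' @param total_mass_kg Total mass of beans and solution, kg (> 0).
#' @return Specific energy input, kJ/kg.
#' @examples
#' specific_energy(1, 1000, 0.5)  # 2 kJ/kg
#' @export
specific_energy <- function(pulse_energy_j, pulse_count, total_mass_kg) {
  check_positive_scalar(total_mass_kg, "total_mass_kg")
  if (any(pulse_energy_j < 0) || any(pulse_count < 0)) {
    bb_abort("Pulse energy and count must be non-negative.",
             "beanbolus_parameter_error")
  }
  pulse_energy_j * pulse_count / total_mass_kg / 1000
}

#' Treatment time of a pulsed electric field protocol
#'
#' The effective treatment time is `pulse_count * pulse_width`, reported in
#' milliseconds.
#'
#' @param pulse_count Number of pulses (>= 0).
#' @param pulse_width_us Pulse width, microseconds (>= 0).
#' @return Treatment time, ms.
#' @examples
#' treatment_time(2000, 20)  # 40 ms
#' @export
treatment_time <- function(pulse_count, pulse_width_us) {
  if (any(pulse_count < 0) || any(pulse_width_us < 0)) {
    bb_abort("Pulse count and width must be non-negative.",
             "beanbolus_parameter_error")
  }
  pulse_count * pulse_width_us / 1000
}

#' Texture profile analysis of a double-compression force curve
#'
#' Splits the curve into its two compression cycles (contiguous runs of force
#' above `force_threshold`), locates each cycle's peak, and computes the
#' standard two-bite parameters from force-time integration:
#' * hardness: peak force of cycle 1 (N);
#' * cohesiveness: area under cycle 2 / area under cycle 1;
#' * springiness: compression (downstroke) duration of cycle 2 / cycle 1;
#' * chewiness: hardness x cohesiveness x springiness (N);
#' * resilience: cycle-1 withdrawal area / cycle-1 compression area.
#'
#' @param curve Tibble with `time_s` and `force_n` columns.
#' @param force_threshold Trigger force separating cycles from baseline, N.
#' @param min_run Minimum number of consecutive above-threshold samples for a
#'   run to count as a compression cycle (trigger hysteresis against sensor
#'   noise spikes).
#' @return A one-row tibble: `hardness`, `cohesiveness`, `springiness`,
#'   `chewiness`, `resilience`.
#' @examples
#' compute_tpa(simulate_tpa_curve(10, 0.5, 0.8))
#' @export
compute_tpa <- function(curve, force_threshold = 0.049, min_run = 5) {
  t <- curve[["time_s"]] %||% curve[["time"]]
  f <- curve[["force_n"]] %||% curve[["force"]]
  if (is.null(t) || is.null(f)) {
    bb_abort("Curve must have `time_s` and `force_n` columns.",
             "beanbolus_parameter_error")
  }
  above <- f > force_threshold
  r <- rle(above)
  run_id <- rep(seq_along(r$lengths), r$lengths)
  long_enough <- r$lengths >= min_run
  cycles <- which(r$values & long_enough)
  if (length(cycles) != 2) {
    bb_abort(sprintf(
      "Expected two compression cycles above the trigger force, found %d.",
      length(cycles)), "beanbolus_tpa_error")
  }
  cycle_stats <- lapply(cycles, function(cid) {
    i <- which(run_id == cid)
    ti <- t[i]; fi <- f[i]
    peak <- which.max(fi)
    list(
      peak_force = max(fi),
      area = trapezoid(ti, fi),
      comp_area = trapezoid(ti[1:peak], fi[1:peak]),
      withd_area = trapezoid(ti[peak:length(ti)], fi[peak:length(ti)]),
      comp_duration = ti[peak] - ti[1]
    )
  })
  c1 <- cycle_stats[[1]]; c2 <- cycle_stats[[2]]
  hardness <- c1$peak_force
  cohesiveness <- c2$area / c1$area
  springiness <- c2$comp_duration / c1$comp_duration
  tibble::tibble(
    hardness = hardness,
    cohesiveness = cohesiveness,
    springiness = springiness,
    chewiness = hardness * cohesiveness * springiness,
    resilience = c1$withd_area / c1$comp_area
  )
}

#' Full quadratic response-surface design matrix
#'
#' Expands three processing factors into the ten model columns of a full
#' quadratic response surface: intercept, main effects, two-way interactions
#' and squared terms. Factors are used on their raw scale by default;
#' `centre = TRUE` centres them first.
#'
#' @param inputs Data frame (or matrix) with three numeric columns: field
#'   strength, specific energy input and calcium concentration (any names).
#' @param centre Centre the factors before expansion?
#' @return A numeric matrix with columns `intercept`, `x1`, `x2`, `x3`,
#'   `x1:x2`, `x1:x3`, `x2:x3`, `x1^2`, `x2^2`, `x3^2`. If the matrix has
#'   fewer rows than columns or is rank deficient, attribute `"full_rank"` is
#'   `FALSE`.
#' @examples
#' build_design_matrix(data.frame(fs = 1, e = 2, ca = 3))
#' @export
build_design_matrix <- function(inputs, centre = FALSE) {
  X0 <- as.matrix(inputs)
  if (ncol(X0) != 3) {
    bb_abort("Exactly three input factors are required.", "beanbolus_parameter_error")
  }
  storage.mode(X0) <- "double"
  if (centre) X0 <- scale(X0, center = TRUE, scale = FALSE)
  x1 <- X0[, 1]; x2 <- X0[, 2]; x3 <- X0[, 3]
  X <- cbind(
    intercept = 1, x1 = x1, x2 = x2, x3 = x3,
    "x1:x2" = x1 * x2, "x1:x3" = x1 * x3, "x2:x3" = x2 * x3,
    "x1^2" = x1^2, "x2^2" = x2^2, "x3^2" = x3^2
  )
  attr(X, "full_rank") <- qr(X)$rank == ncol(X)
  X
}

#' Fit the quadratic response-surface model by least squares
#'
#' Ordinary least squares of a texture response on the full quadratic
#' expansion of the three processing factors, with per-coefficient standard
#' errors and two-sided t-test p-values (screening use: no multiplicity
#' adjustment).
#'
#' @param inputs Data frame of the three factors (rows are runs), or a design
#'   matrix from [build_design_matrix()].
#' @param response Numeric response vector (one value per run).
#' @param centre Passed to [build_design_matrix()] when `inputs` is raw.
#' @return An `rsm_fit` object; [tidy()] gives the coefficient table
#'   (`term`, `estimate`, `std_error`, `p_value`), [glance()] the model-level
#'   summary.
#' @export
fit_rsm <- function(inputs, response, centre = FALSE) {
  X <- if (is.matrix(inputs) && "intercept" %in% colnames(inputs)) {
    inputs
  } else {
    build_design_matrix(inputs, centre = centre)
  }
  y <- as.numeric(response)
  if (nrow(X) < ncol(X)) {
    bb_abort("Need at least as many runs as model terms (10).",
             "beanbolus_fit_error")
  }
  if (!isTRUE(attr(X, "full_rank") %||% (qr(X)$rank == ncol(X)))) {
    bb_abort("Design matrix is rank deficient; the quadratic model is not estimable.",
             "beanbolus_fit_error")
  }
  fit <- lm(y ~ X - 1)
  sm <- summary(fit)
  coefs <- sm$coefficients
  structure(
    list(
      coefficients = tibble::tibble(
        term = colnames(X),
        estimate = unname(coefs[, 1]),
        std_error = unname(coefs[, 2]),
        p_value = unname(coefs[, 4])
      ),
      sigma = sm$sigma,
      r_squared = sm$r.squared,
      adj_r2 = sm$adj.r.squared,
      df_residual = fit$df.residual,
      n = nrow(X),
      centre = centre,
      centre_values = if (centre) attr(X, "scaled:center") else NULL,
      model = fit
    ),
    class = "rsm_fit"
  )
}

#' @export
print.rsm_fit <- function(x, ...) {
  cat(sprintf("Quadratic response-surface fit (%d runs, R^2 = %.4f)\n",
              x$n, x$r_squared))
  print(as.data.frame(x$coefficients), digits = 4)
  invisible(x)
}

#' @method tidy rsm_fit
#' @export
tidy.rsm_fit <- function(x, ...) x$coefficients

#' @method glance rsm_fit
#' @export
glance.rsm_fit <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, adj_r2 = x$adj_r2,
                 sigma = x$sigma, n = x$n, df_residual = x$df_residual)
}

#' Prediction profile across one factor
#'
#' Evaluates the fitted response surface along a grid of one factor while the
#' other two are held at fixed values — the cross-sectional view used to
#' screen how a single processing input drives a texture response.
#'
#' @param fit An `rsm_fit`.
#' @param vary Which factor to vary: `"x1"`, `"x2"` or `"x3"`.
#' @param grid Numeric grid of values for the varied factor.
#' @param fixed Named values for the two held factors, e.g.
#'   `c(x2 = 10, x3 = 300)`.
#' @return A tibble with the grid and the `predicted` response.
#' @export
prediction_profile <- function(fit, vary, grid, fixed) {
  stopifnot(inherits(fit, "rsm_fit"))
  factors <- c("x1", "x2", "x3")
  if (!vary %in% factors) {
    bb_abort(sprintf("Unknown factor '%s'; use one of %s.", vary,
                     paste(factors, collapse = ", ")),
             "beanbolus_parameter_error")
  }
  held <- setdiff(factors, vary)
  if (!all(held %in% names(fixed))) {
    bb_abort(sprintf("`fixed` must name the held factors: %s.",
                     paste(held, collapse = ", ")),
             "beanbolus_parameter_error")
  }
  pts <- tibble::tibble(!!vary := grid,
                        !!held[1] := fixed[[held[1]]],
                        !!held[2] := fixed[[held[2]]])
  pts <- pts[, factors]
  X <- build_design_matrix(pts)
  if (isTRUE(fit$centre)) {
    X <- build_design_matrix(sweep(as.matrix(pts), 2, fit$centre_values))
  }
  pred <- as.numeric(X %*% fit$coefficients$estimate)
  dplyr::mutate(pts, predicted = pred)
}
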