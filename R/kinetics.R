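#' Glucose-to-starch conversion factor
#'
#' Measured D-glucose is converted to anhydroglucose (polysaccharide) mass by
#' the molecular-mass ratio of a starch monomer unit to free glucose,
#' 162/180 = 0.9.
#'
#' @return The scalar 162/180.
#' @export
starch_conversion_factor <- function() 162 / 180

#' Fractional conversion model for starch digestion
#'
#' First-order approach of released D-glucose from its initial amount `S0`
#' towards the final plateau `Sf`:
#' \deqn{S(t) = S_f + (S_0 - S_f)\, e^{-k_s t}}
#' The rate constant `ks` is positive for rising curves; the exponent decays,
#' so `S` increases monotonically from `S0` to `Sf` when `Sf > S0`.
#'
#' @param t Digestion time(s), min.
#' @param s0 D-glucose at the start of the intestinal phase, mg (>= 0).
#' @param sf D-glucose at the end of digestion, mg (>= `s0`).
#' @param ks Rate constant, min^-1 (> 0).
#' @return Predicted D-glucose, mg.
#' @examples
#' fractional_conversion(60, s0 = 78.4, sf = 196.4, ks = 0.027)
#' @export
fractional_conversion <- function(t, s0, sf, ks) {
  check_positive_scalar(ks, "ks")
  check_positive_scalar(s0, "s0", strict = FALSE)
  if (sf < s0) {
    bb_abort("`sf` must be at least `s0` for an increasing digestion curve.",
             "beanbolus_parameter_error")
  }
  sf + (s0 - sf) * exp(-ks * t)
}

series_columns <- function(series) {
  t <- series[["time_min"]] %||% series[["t"]]
  v <- series[["value_mg"]] %||% series[["value"]]
  if (is.null(t) || is.null(v)) {
    bb_abort("Series must have time (`time_min`) and value (`value_mg`) columns.",
             "beanbolus_parameter_error")
  }
  list(t = as.numeric(t), v = as.numeric(v))
}

adj_r_squared <- function(obs, pred, n_par) {
  n <- length(obs)
  if (n <= n_par + 1) {
    bb_abort("Adjusted R-squared undefined: need more points than parameters + 1.",
             "beanbolus_fit_error")
  }
  ss_res <- sum((obs - pred)^2)
  ss_tot <- sum((obs - mean(obs))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  1 - (1 - r2) * (n - 1) / (n - n_par - 1)
}

new_kinetics_fit <- function(subclass, params, obs, t, pred, converged) {
  structure(
    list(
      params = params,
      n = length(obs),
      # undefined with n <= p + 1 (e.g. a 3-point zero-order line); the
      # diagnostics accessor turns that NA into an explicit error
      adj_r2 = if (length(obs) > length(params) + 1) {
        adj_r_squared(obs, pred, length(params))
      } else {
        NA_real_
      },
      converged = converged,
      data = tibble::tibble(time_min = t, observed = obs, predicted = pred)
    ),
    class = c(subclass, "kinetics_fit")
  )
}

#' Fit the fractional conversion model to an intestinal starch time course
#'
#' Least-squares estimation of `(S0, Sf, ks)` with positivity (and
#' `Sf >= S0`) enforced by optimising `log S0`, `log(Sf - S0)` and `log ks`
#' with BFGS. Default initial values: `S0` from the first observation, `Sf`
#' from the largest, and `ks` from a log-linear regression of
#' `log(Sf_init - S)` on `t`. Non-convergence is flagged, never silent.
#'
#' @param series A digestion time series (tibble with `time_min` and
#'   `value_mg`, e.g. from [simulate_digesta()]) with at least 4 points.
#' @param init Optional starting values `c(s0, sf, ks)`.
#' @param tol Relative convergence tolerance.
#' @param max_iter Maximum optimiser iterations.
#' @return A `starch_fit` object with elements `params` (`s0`, `sf`, `ks`),
#'   `adj_r2`, `converged` and the observed/predicted data. Supports
#'   [tidy()], [glance()], [augment()] and [autoplot()].
#' @examples
#' ts <- simulate_digesta("fractional_conversion",
#'                        params = list(s0 = 78.4, sf = 196.4, ks = 0.027))
#' glance(fit_fractional_conversion(ts))
#' @export
fit_fractional_conversion <- function(series, init = NULL, tol = 1e-12,
                                      max_iter = 1000) {
  sc <- series_columns(series)
  t <- sc$t; v <- sc$v
  if (length(t) < 4) {
    bb_abort("Fractional conversion fitting needs at least 4 points.",
             "beanbolus_fit_error")
  }
  fit0 <- lm(v ~ t)
  if (coef(fit0)[2] < 0 && v[length(v)] < v[1]) {
    bb_abort("Series decreases over time; the fractional conversion model does not apply.",
             "beanbolus_fit_error")
  }
  if (is.null(init)) {
    s0_init <- max(v[1], 1e-6)
    sf_init <- max(v) * 1.02
    gap <- pmax(sf_init - v, sf_init * 1e-4)
    ks_init <- max(-coef(lm(log(gap) ~ t))[2], 1e-4)
    init <- c(s0_init, sf_init, ks_init)
  }
  theta0 <- c(log(max(init[1], 1e-8)),
              log(max(init[2] - init[1], 1e-8)),
              log(init[3]))
  obj <- function(th) {
    s0 <- exp(th[1]); sf <- s0 + exp(th[2]); ks <- exp(th[3])
    sum((v - (sf + (s0 - sf) * exp(-ks * t)))^2)
  }
  opt <- optim(theta0, obj, method = "BFGS",
               control = list(maxit = max_iter, reltol = tol))
  # polish with Nelder-Mead in case BFGS stalled on a flat log-scale ridge
  opt2 <- optim(opt$par, obj, method = "Nelder-Mead",
                control = list(maxit = max_iter, reltol = tol))
  if (opt2$value < opt$value) opt <- opt2
  s0 <- exp(opt$par[1]); sf <- s0 + exp(opt$par[2]); ks <- exp(opt$par[3])
  pred <- sf + (s0 - sf) * exp(-ks * t)
  new_kinetics_fit("starch_fit", c(s0 = s0, sf = sf, ks = ks),
                   v, t, pred, opt$convergence == 0L)
}

#' Fit zero-order kinetics to an intestinal protein time course
#'
#' Ordinary least-squares line `P(t) = P0 + kp t` fitted with [lm()]. The
#' slope `kp` is in mg/min; [glance()] also reports `kp_e2_per_min`
#' (`kp x 100`), the presentation scale customary for these digestion rates.
#'
#' @param series A digestion time series with at least 3 points.
#' @return A `protein_fit` object (`params` holding `p0` and `kp`, `adj_r2`,
#'   observed/predicted data).
#' @examples
#' ts <- simulate_digesta("zero_order", params = list(p0 = 50, kp = 0.1))
#' tidy(fit_zero_order(ts))
#' @export
fit_zero_order <- function(series) {
  sc <- series_columns(series)
  if (length(sc$t) < 3) {
    bb_abort("Zero-order fitting needs at least 3 points.", "beanbolus_fit_error")
  }
  fit <- lm(v ~ t, data = list(v = sc$v, t = sc$t))
  new_kinetics_fit("protein_fit",
                   c(p0 = unname(coef(fit)[1]), kp = unname(coef(fit)[2])),
                   sc$v, sc$t, unname(stats::fitted(fit)), TRUE)
}

#' @export
print.kinetics_fit <- function(x, ...) {
  cat(sprintf("%s kinetics fit (n = %d)\n",
              if (inherits(x, "starch_fit")) "Fractional conversion" else "Zero-order",
              x$n))
  print(round(x$params, 5))
  cat(sprintf("  adjusted R^2 = %.4f%s\n", x$adj_r2,
              if (x$converged) "" else "  [did not converge]"))
  invisible(x)
}

#' @method tidy kinetics_fit
#' @export
tidy.kinetics_fit <- function(x, ...) {
  tibble::tibble(term = names(x$params), estimate = unname(x$params))
}

#' @method glance kinetics_fit
#' @export
glance.kinetics_fit <- function(x, ...) {
  out <- tibble::as_tibble(as.list(x$params))
  out$adj_r2 <- x$adj_r2
  out$n <- x$n
  out$converged <- x$converged
  if (inherits(x, "protein_fit")) out$kp_e2_per_min <- out$kp * 100
  if (inherits(x, "starch_fit")) out$ks_e2_per_min <- out$ks * 100
  out
}

#' @method augment kinetics_fit
#' @export
augment.kinetics_fit <- function(x, ...) {
  dplyr::mutate(x$data, residual = .data$observed - .data$predicted)
}

#' @method autoplot kinetics_fit
#' @export
autoplot.kinetics_fit <- function(object, ...) {
  dat <- object$data
  ggplot2::ggplot(dat, ggplot2::aes(.data$time_min)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$predicted), colour = "red3") +
    ggplot2::labs(x = "Small intestinal digestion time (min)",
                  y = "Analyte in digest (mg)")
}

#' Goodness-of-fit diagnostics for a kinetics fit
#'
#' @param fit A `starch_fit` or `protein_fit`.
#' @return A list with `adj_r2`, a `residuals` tibble (`time_min`,
#'   `residual`) and a `parity` tibble (`observed`, `predicted`).
#' @export
fit_diagnostics <- function(fit) {
  stopifnot(inherits(fit, "kinetics_fit"))
  if (is.na(fit$adj_r2)) {
    bb_abort("Adjusted R-squared undefined: need more points than parameters + 1.",
             "beanbolus_fit_error")
  }
  aug <- augment(fit)
  list(
    adj_r2 = fit$adj_r2,
    residuals = dplyr::select(aug, "time_min", "residual"),
    parity = dplyr::select(aug, "observed", "predicted")
  )
}

#' Starch fractions from intestinal glucose release
#'
#' Rapidly digestible starch (RDS) is the starch digested within the first
#' 20 min of the intestinal phase, slowly digestible starch (SDS) between 20
#' and 120 min, and resistant starch (RS) the remainder that passes through
#' undigested:
#' \deqn{RDS\% = G_{20} \cdot 0.9 \cdot 100 / TS, \quad
#'       SDS\% = (G_{120} - G_{20}) \cdot 0.9 \cdot 100 / TS, \quad
#'       RS\% = 100 - RDS\% - SDS\%}
#' with 0.9 = 162/180 the glucose-to-starch conversion factor
#' ([starch_conversion_factor()]).
#'
#' @param g20,g120 D-glucose released after 20 and 120 min of intestinal
#'   digestion, mg (`g120 >= g20 >= 0`). Vectorised.
#' @param total_starch Total starch of the bolus, mg (> 0); digested starch
#'   `0.9 * g120` may not exceed it.
#' @return A tibble with columns `g20`, `g120`, `total_starch`, `rds`, `sds`,
#'   `rs` (percentages summing to 100).
#' @examples
#' starch_fractions(g20 = 10, g120 = 10, total_starch = 90)
#' @export
starch_fractions <- function(g20, g120, total_starch) {
  if (any(total_starch <= 0)) {
    bb_abort("`total_starch` must be positive.", "beanbolus_parameter_error")
  }
  if (any(g20 < 0)) {
    bb_abort("`g20` must be non-negative.", "beanbolus_parameter_error")
  }
  if (any(g120 < g20)) {
    bb_abort("`g120` must be at least `g20`: glucose release cannot decrease.",
             "beanbolus_parameter_error")
  }
  f <- starch_conversion_factor()
  if (any(f * g120 > total_starch * (1 + 1e-9))) {
    bb_abort("Digested starch (0.9 * g120) exceeds `total_starch`.",
             "beanbolus_parameter_error")
  }
  rds <- g20 * f * 100 / total_starch
  sds <- (g120 - g20) * f * 100 / total_starch
  tibble::tibble(
    g20 = g20, g120 = g120, total_starch = total_starch,
    rds = rds, sds = sds, rs = resistant_fraction(rds, sds)
  )
}

#' Resistant starch from the two digestible fractions
#'
#' The three fractions partition total starch, so the resistant fraction is
#' the complement of the digestible ones: `RS% = 100 - RDS% - SDS%`. Useful
#' for recovering RS from reported RDS and SDS percentages.
#'
#' @param rds,sds RDS and SDS percentages.
#' @return RS percentage(s).
#' @examples
#' resistant_fraction(37.7, 21.8)
#' @export
resistant_fraction <- function(rds, sds) {
  if (any(rds < 0) || any(sds < 0) || any(rds + sds > 100 + 1e-9)) {
    bb_abort("`rds` and `sds` must be non-negative and sum to at most 100.",
             "beanbolus_parameter_error")
  }
  100 - rds - sds
}

#' Gastric-phase endpoints
#'
#' The gastric phase is summarised descriptively by the glucose sampled at
#' its start (0 min, i.e. the end of oral mastication) and at its completion
#' (120 min); no kinetic model is fitted in this phase.
#'
#' @param series A gastric-phase time series containing `time_min` 0 and 120.
#' @return A tibble with columns `value_0`, `value_120` (mg).
#' @export
gastric_endpoints <- function(series) {
  sc <- series_columns(series)
  i0 <- which(sc$t == 0)
  i120 <- which(sc$t == 120)
  if (length(i0) != 1 || length(i120) != 1) {
    bb_abort("Gastric series must contain exactly one sample at 0 and one at 120 min.",
             "beanbolus_parameter_error")
  }
  tibble::tibble(value_0 = sc$v[i0], value_120 = sc$v[i120])
}
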