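#' Rosin-Rammler cumulative area distribution
#'
#' The Rosin-Rammler law describes the cumulative area fraction of comminuted
#' particles up to area `x` as
#' \deqn{C(x) = 1 - \exp\{-(x/x_{50})^b \ln 2\}}
#' where `x50` is the median particle area (the area at which half of the
#' total particle area is carried by smaller particles) and `b` is the
#' dimensionless breadth constant: a larger `b` gives a narrower spread.
#'
#' @param x Particle area(s), mm^2 (non-negative).
#' @param x50 Median particle area, mm^2 (> 0).
#' @param b Distribution breadth constant (> 0).
#' @return `rr_cdf()` returns cumulative area fractions in `[0, 1]`;
#'   `rr_quantile()` returns the areas at which the cumulative fraction
#'   reaches `p`.
#' @examples
#' rr_cdf(5, x50 = 5, b = 1.6)     # 0.5 by definition of the median
#' rr_quantile(0.5, x50 = 5, b = 1.6)
#' @export
rr_cdf <- function(x, x50, b) {
  check_positive_scalar(x50, "x50")
  check_positive_scalar(b, "b")
  if (any(x < 0)) {
    bb_abort("Particle areas `x` must be non-negative.", "beanbolus_parameter_error")
  }
  1 - exp(-(x / x50)^b * log(2))
}

#' @param p Cumulative area fraction(s) in `[0, 1)`.
#' @rdname rr_cdf
#' @export
rr_quantile <- function(p, x50, b) {
  check_positive_scalar(x50, "x50")
  check_positive_scalar(b, "b")
  if (any(p < 0 | p >= 1)) {
    bb_abort("`p` must lie in [0, 1).", "beanbolus_parameter_error")
  }
  x50 * (-log(1 - p) / log(2))^(1 / b)
}

#' Build the cumulative particle-area distribution
#'
#' Sorts particle areas ascending and accumulates, with ties kept as separate
#' points. Two weighting conventions are supported:
#'
#' * `"area"` (default): the value attached to each particle is the fraction
#'   of the *total particle area* carried by particles of that size or
#'   smaller — the undersize convention under which the Rosin-Rammler model
#'   describes measured bolus plates (its median cuts 50 percent of the total
#'   cumulative weight of the food particles).
#' * `"count"`: the plain empirical CDF `i/n`. This is the right curve when
#'   the areas are inverse-CDF draws of the Rosin-Rammler law itself (e.g.
#'   from [sample_rosin_rammler()]), whose *count*-weighted CDF converges to
#'   the model; re-weighting such draws by area would size-bias the curve and
#'   inflate the fitted median.
#'
#' @param areas Positive particle areas, mm^2.
#' @param weighting `"area"` or `"count"` (see above).
#' @return A tibble with columns `area_mm2` (sorted ascending) and `c_area`
#'   (cumulative fraction, ending at 1).
#' @examples
#' build_cumulative(c(4, 1, 3, 2))
#' @export
build_cumulative <- function(areas, weighting = c("area", "count")) {
  weighting <- match.arg(weighting)
  areas <- as.numeric(areas)
  if (length(areas) == 0L || any(!is.finite(areas)) || any(areas <= 0)) {
    bb_abort("`areas` must be a non-empty vector of positive finite areas.",
             "beanbolus_parameter_error")
  }
  areas <- sort(areas)
  tibble::tibble(
    area_mm2 = areas,
    c_area = if (weighting == "area") {
      cumsum(areas) / sum(areas)
    } else {
      seq_along(areas) / length(areas)
    }
  )
}

#' Fit the Rosin-Rammler model to a cumulative area distribution
#'
#' Estimates the median particle area `x50` and breadth `b` by unweighted
#' least squares on the cumulative area fractions. Positivity of both
#' parameters is enforced by optimising on the log scale with a quasi-Newton
#' method (BFGS), so no constraint handling is needed. The default starting
#' point is the empirical area-weighted median for `x50` and `b = 1.5`.
#'
#' @param dist A tibble from [build_cumulative()], or a bare numeric vector of
#'   particle areas (which is passed through [build_cumulative()] first).
#' @param init Optional starting values, `c(x50, b)`.
#' @param tol Convergence tolerance passed to the optimiser.
#' @param max_iter Maximum number of optimiser iterations.
#' @param weighting Cumulative-curve convention used when `dist` is a bare
#'   vector of areas; see [build_cumulative()].
#' @return An object of class `rr_fit`: a list with elements `x50`, `b`,
#'   `rss`, `n`, `converged`, `class_scope` and the fitted distribution.
#' @examples
#' areas <- rr_quantile(stats::ppoints(200), x50 = 5, b = 1.6)
#' fit_rosin_rammler(areas, weighting = "count")
#' @export
fit_rosin_rammler <- function(dist, init = NULL, tol = 1e-10, max_iter = 500,
                              weighting = c("area", "count")) {
  if (is.numeric(dist)) dist <- build_cumulative(dist, weighting = weighting)
  stopifnot(all(c("area_mm2", "c_area") %in% names(dist)))
  x <- dist$area_mm2
  y <- dist$c_area
  if (length(unique(x)) < 3L) {
    bb_abort("Rosin-Rammler fitting needs at least 3 distinct particle areas.",
             "beanbolus_fit_error")
  }
  if (is.null(init)) {
    # empirical area-weighted median: first area at which c_area >= 0.5
    init <- c(x[which(y >= 0.5)[1]], 1.5)
  }
  check_positive_scalar(init[1], "init[x50]")
  check_positive_scalar(init[2], "init[b]")

  obj <- function(theta) {
    pred <- 1 - exp(-(x / exp(theta[1]))^exp(theta[2]) * log(2))
    sum((y - pred)^2)
  }
  opt <- optim(log(init), obj, method = "BFGS",
               control = list(maxit = max_iter, reltol = tol))
  structure(
    list(
      x50 = exp(opt$par[1]),
      b = exp(opt$par[2]),
      rss = opt$value,
      n = length(x),
      converged = opt$convergence == 0L,
      class_scope = "all",
      distribution = dist
    ),
    class = "rr_fit"
  )
}

#' @export
print.rr_fit <- function(x, ...) {
  cat(sprintf(
    "Rosin-Rammler fit (%s particles, scope '%s')\n  x50 = %.3f mm^2, b = %.3f, RSS = %.3g%s\n",
    x$n, x$class_scope, x$x50, x$b, x$rss,
    if (x$converged) "" else "  [did not converge]"
  ))
  invisible(x)
}

#' @method tidy rr_fit
#' @export
tidy.rr_fit <- function(x, ...) {
  tibble::tibble(
    term = c("x50", "b"),
    estimate = c(x$x50, x$b)
  )
}

#' @method glance rr_fit
#' @export
glance.rr_fit <- function(x, ...) {
  tibble::tibble(
    x50 = x$x50, b = x$b, rss = x$rss, n = x$n,
    converged = x$converged, class_scope = x$class_scope
  )
}

#' @method autoplot rr_fit
#' @export
autoplot.rr_fit <- function(object, ...) {
  dist <- object$distribution
  grid <- tibble::tibble(
    area_mm2 = seq(0, max(dist$area_mm2), length.out = 200),
    c_area = rr_cdf(seq(0, max(dist$area_mm2), length.out = 200),
                    object$x50, object$b)
  )
  ggplot2::ggplot(dist, ggplot2::aes(.data$area_mm2, .data$c_area)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_line(data = grid, colour = "red3") +
    ggplot2::labs(
      x = expression("Particle area (mm"^2 * ")"),
      y = "Cumulative area fraction",
      title = sprintf("Rosin-Rammler fit: x50 = %.2f mm^2, b = %.2f",
                      object$x50, object$b)
    )
}

#' Fit Rosin-Rammler distributions per bolus and colour class
#'
#' Runs [fit_rosin_rammler()] on all particles together and separately on the
#' seed-coat ("black") and cotyledon ("white") classes for each bolus. Class
#' scopes with fewer than three particles are reported as a flagged row with
#' `NA` parameters rather than silently dropped.
#'
#' @param particles A particle table with at least `area_mm2` and `class`
#'   columns (as produced by the imaging pipeline); an optional `bolus_id`
#'   column splits the fits by bolus.
#' @param by_class Also fit each colour class separately? Default `TRUE`.
#' @param weighting Cumulative-curve convention, see [build_cumulative()].
#' @return A tibble with one row per bolus and class scope: `bolus_id`,
#'   `class_scope` (`"all"`, `"black"`, `"white"`), `x50_mm2`, `b`, `rss`,
#'   `n_particles`, `converged`.
#' @export
fit_psd <- function(particles, by_class = TRUE,
                    weighting = c("area", "count")) {
  weighting <- match.arg(weighting)
  stopifnot(is.data.frame(particles), "area_mm2" %in% names(particles))
  if (!"bolus_id" %in% names(particles)) particles$bolus_id <- "bolus"
  scopes <- if (by_class && "class" %in% names(particles)) {
    c("all", "black", "white")
  } else {
    "all"
  }
  grid <- tidyr::expand_grid(
    bolus_id = unique(particles$bolus_id),
    class_scope = scopes
  )
  purrr::pmap_dfr(grid, function(bolus_id, class_scope) {
    sub <- particles[particles$bolus_id == bolus_id, , drop = FALSE]
    if (class_scope != "all") sub <- sub[sub$class == class_scope, , drop = FALSE]
    if (nrow(sub) < 3L || length(unique(sub$area_mm2)) < 3L) {
      return(tibble::tibble(
        bolus_id = bolus_id, class_scope = class_scope,
        x50_mm2 = NA_real_, b = NA_real_, rss = NA_real_,
        n_particles = nrow(sub), converged = FALSE
      ))
    }
    fit <- fit_rosin_rammler(sub$area_mm2, weighting = weighting)
    tibble::tibble(
      bolus_id = bolus_id, class_scope = class_scope,
      x50_mm2 = fit$x50, b = fit$b, rss = fit$rss,
      n_particles = fit$n, converged = fit$converged
    )
  })
}
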