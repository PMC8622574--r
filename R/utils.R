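# Internal helpers shared across modules.

# Stop with a classed condition so callers/tests can match on error class.
bb_abort <- function(message, class) {
  rlang::abort(message, class = c(class, "beanbolus_error"))
}

check_positive_scalar <- function(x, name, strict = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (strict) x > 0 else x >= 0)
  if (!ok) {
    bb_abort(
      sprintf("`%s` must be a %s finite number, not %s.",
              name, if (strict) "positive" else "non-negative",
              paste(format(x), collapse = ", ")),
      "beanbolus_parameter_error"
    )
  }
  invisible(x)
}

# Rec.601 luminance on the same scale as the input channels.
luminance <- function(r, g, b) 0.299 * r + 0.587 * g + 0.114 * b

# Trapezoidal integral of y over x.
trapezoid <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum(diff(x) * (y[-1] + y[-n]) / 2)
}

# Run code with a local RNG state seeded from `seed`; restores the caller's
# RNG so generators never perturb the session stream.
with_local_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}
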