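# Independent brute-force oracles used to cross-check the package's fitting
# routines, plus shared synthetic fixtures built once per test run.

# Grid-search least squares for the Rosin-Rammler parameters: exhaustive over
# a (x50, b) grid, successively refined around the incumbent.
rr_grid_oracle <- function(x, y, x50_range = c(0.5, 20), b_range = c(0.3, 5),
                           steps = 41, refinements = 4) {
  best <- c(NA, NA, Inf)
  for (r in seq_len(refinements)) {
    x50s <- seq(x50_range[1], x50_range[2], length.out = steps)
    bs <- seq(b_range[1], b_range[2], length.out = steps)
    for (x50 in x50s) {
      for (b in bs) {
        rss <- sum((y - (1 - exp(-(x / x50)^b * log(2))))^2)
        if (rss < best[3]) best <- c(x50, b, rss)
      }
    }
    dx <- diff(x50_range) / (steps - 1)
    db <- diff(b_range) / (steps - 1)
    x50_range <- c(best[1] - dx, best[1] + dx)
    b_range <- c(max(best[2] - db, 1e-3), best[2] + db)
  }
  list(x50 = best[1], b = best[2], rss = best[3])
}

# Exhaustive 3-D grid search for the fractional conversion parameters.
fc_grid_oracle <- function(t, v, s0_range, sf_range, ks_range,
                           steps = 21, refinements = 4) {
  best <- c(NA, NA, NA, Inf)
  for (r in seq_len(refinements)) {
    for (s0 in seq(s0_range[1], s0_range[2], length.out = steps)) {
      for (sf in seq(sf_range[1], sf_range[2], length.out = steps)) {
        for (ks in seq(ks_range[1], ks_range[2], length.out = steps)) {
          if (sf < s0) next
          rss <- sum((v - (sf + (s0 - sf) * exp(-ks * t)))^2)
          if (rss < best[4]) best <- c(s0, sf, ks, rss)
        }
      }
    }
    shrink <- function(range, centre) {
      d <- diff(range) / (steps - 1)
      c(centre - d, centre + d)
    }
    s0_range <- shrink(s0_range, best[1])
    sf_range <- shrink(sf_range, best[2])
    ks_range <- pmax(shrink(ks_range, best[3]), 1e-6)
  }
  list(s0 = best[1], sf = best[2], ks = best[3], rss = best[4])
}

# Textbook covariance-formula Pearson correlation.
pearson_oracle <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Closed-form normal-equation least squares.
normal_equations_oracle <- function(X, y) {
  solve(t(X) %*% X, t(X) %*% y)[, 1]
}

# Shared rendered plate fixtures (rendering is the slow step; build once).
plate_fixture <- local({
  cache <- list()
  function(name = c("clean", "reflective")) {
    name <- match.arg(name)
    if (is.null(cache[[name]])) {
      cache[[name]] <<- switch(name,
        clean = simulate_plate(plate_spec(
          n_white = 20, n_black = 10, image_size_px = 800, seed = 101
        )),
        reflective = simulate_plate(plate_spec(
          n_white = 15, n_black = 8, n_reflections = 5,
          image_size_px = 800, seed = 202
        ))
      )
    }
    cache[[name]]
  }
})

fixture_calibration <- function(render) {
  calibrate(render$calibration$marker_length_mm,
            render$calibration$marker_length_px)
}

# Match detected records to ground-truth rows by nearest centroid.
match_truth <- function(records, truth) {
  vapply(seq_len(nrow(records)), function(i) {
    which.min((truth$centroid_x_px - records$centroid_x_px[i])^2 +
                (truth$centroid_y_px - records$centroid_y_px[i])^2)
  }, integer(1))
}
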