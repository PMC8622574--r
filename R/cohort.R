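#' Classify participants into fast, slow and inconsistent chewers
#'
#' For each sample the cohort median chewing duration is computed across
#' participants (midpoint of the two central order statistics for even
#' counts). A participant is a *slow* chewer if their duration is strictly
#' above the median for every sample, a *fast* chewer if it is at or below
#' the median for every sample, and *inconsistent* otherwise. The median
#' participant is thereby grouped with the fast chewers — a cohort of
#' observed durations always contains a participant sitting on the median
#' line, and classifying against a strict two-sided rule would force them
#' (and with them the counts) off any clean fast/slow split.
#'
#' @param panel Long tibble with `participant_id`, `sample`, `duration_s`
#'   (one row per participant and sample, e.g. from [simulate_panel()]), or a
#'   wide data frame whose first column is `participant_id` and remaining
#'   columns are per-sample durations.
#' @param reference_medians Optional named per-sample medians to classify
#'   against instead of the empirical ones.
#' @return A tibble with `participant_id` and `class`; the per-sample medians
#'   used are attached as attribute `"sample_medians"` (a named numeric
#'   vector) and returned by [chewer_medians()].
#' @examples
#' panel <- simulate_panel(seed = 1)
#' labels <- classify_chewers(panel)
#' table(labels$class)
#' @export
classify_chewers <- function(panel, reference_medians = NULL) {
  if (!all(c("participant_id", "sample", "duration_s") %in% names(panel))) {
    wide <- as.data.frame(panel)
    panel <- tidyr::pivot_longer(wide, -1, names_to = "sample",
                                 values_to = "duration_s")
    names(panel)[1] <- "participant_id"
  }
  if (any(is.na(panel$duration_s))) {
    missing <- unique(panel$participant_id[is.na(panel$duration_s)])
    bb_abort(paste0("Missing durations for participant(s): ",
                    paste(missing, collapse = ", ")),
             "beanbolus_parameter_error")
  }
  if (length(unique(panel$participant_id)) < 2) {
    bb_abort("At least two participants are required.", "beanbolus_parameter_error")
  }
  meds <- if (is.null(reference_medians)) {
    c(tapply(panel$duration_s, panel$sample, median))
  } else {
    reference_medians[sort(unique(panel$sample))]
  }
  labels <- panel |>
    dplyr::mutate(median_s = meds[.data$sample]) |>
    dplyr::summarise(
      class = if (all(.data$duration_s > .data$median_s)) "slow"
              else if (all(.data$duration_s <= .data$median_s)) "fast"
              else "inconsistent",
      .by = "participant_id"
    )
  structure(labels, sample_medians = meds)
}

#' @rdname classify_chewers
#' @param labels A classification result from [classify_chewers()].
#' @export
chewer_medians <- function(labels) attr(labels, "sample_medians")

#' Pearson correlation coefficient
#'
#' Sample Pearson correlation between two metric vectors, with explicit
#' validation: equal lengths of at least 3 and non-degenerate variances.
#'
#' @param x,y Numeric vectors.
#' @return The correlation in `[-1, 1]`.
#' @examples
#' pearson_r(1:10, 2 * (1:10) + 1)  # 1
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    bb_abort("`x` and `y` must have equal length of at least 3.",
             "beanbolus_parameter_error")
  }
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) {
    bb_abort("Fewer than 3 complete observation pairs.", "beanbolus_parameter_error")
  }
  if (var(x) == 0 || var(y) == 0) {
    bb_abort("Correlation undefined: a variable has zero variance.",
             "beanbolus_correlation_error")
  }
  stats::cor(x, y)
}

#' Cross-metric correlation matrix for a participant panel
#'
#' Pairwise Pearson correlations among per-participant metrics (chewing
#' duration, Rosin-Rammler `x50` and `b`, amylase activity, digestion rate
#' constants, starch fractions — whichever are present), using
#' pairwise-complete observations.
#'
#' @param records Data frame with one row per participant and numeric metric
#'   columns; non-numeric columns are ignored.
#' @param metrics Optional character vector restricting which columns enter.
#' @return A symmetric correlation matrix with unit diagonal.
#' @export
correlation_report <- function(records, metrics = NULL) {
  num <- vapply(records, is.numeric, logical(1))
  cols <- names(records)[num]
  if (!is.null(metrics)) cols <- intersect(metrics, cols)
  if (length(cols) < 2) {
    bb_abort("At least two numeric metrics are required.",
             "beanbolus_parameter_error")
  }
  if (nrow(records) < 3) {
    bb_abort("At least three participant records are required.",
             "beanbolus_parameter_error")
  }
  m <- diag(1, length(cols))
  dimnames(m) <- list(cols, cols)
  for (i in seq_along(cols)) {
    for (j in seq_len(i - 1L)) {
      r <- pearson_r(records[[cols[i]]], records[[cols[j]]])
      m[i, j] <- r
      m[j, i] <- r
    }
  }
  m
}
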