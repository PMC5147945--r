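#' Geometric mean fluorescence intensity (FI)
#'
#' `exp(mean(log(v)))` over linear intensities — the FI statistic used to
#' express conjugate brightness. Non-positive values (possible after
#' baseline subtraction in other pipelines) are undefined under the log and
#' are excluded with a warning; when more than 1% of events are excluded the
#' warning flags the statistic as unreliable.
#'
#' @param values Numeric vector of linear intensities, `n >= 1`.
#' @return The geometric mean (scalar).
#' @export
#' @examples
#' geometric_mean(c(10, 1000))  # 100
geometric_mean <- function(values) {
  if (length(values) < 1L) stop("undefined statistic: no values")
  keep <- values > 0
  n_excl <- sum(!keep)
  if (n_excl == length(values)) {
    stop("undefined statistic: all values non-positive")
  }
  if (n_excl > 0) {
    frac <- n_excl / length(values)
    warning(sprintf(
      "geometric_mean: excluded %d non-positive value(s) (%.2f%%)%s",
      n_excl, 100 * frac,
      if (frac > 0.01) " -- statistic flagged unreliable" else ""))
  }
  exp(mean(log(values[keep])))
}

#' Coefficient of variation (percent)
#'
#' `100 * SD / mean` on linear intensities, SD with the n-1 denominator —
#' the peak-width statistic used to judge coupling homogeneity (narrow
#' peaks, low CV). A robust variant `100 * 0.7413 * IQR / median` is
#' available for heavy-tailed acquisitions but is not the default.
#'
#' @param values Numeric vector, `n >= 2`, with positive mean.
#' @param robust Use the IQR-based robust CV instead of SD/mean.
#' @return CV in percent.
#' @export
#' @examples
#' cv_percent(c(1, 3))  # 70.71
cv_percent <- function(values, robust = FALSE) {
  if (length(values) < 2L) stop("undefined statistic: need n >= 2 for CV")
  if (robust) {
    med <- stats::median(values)
    if (med <= 0) stop("undefined statistic: median <= 0")
    return(100 * 0.7413 * stats::IQR(values) / med)
  }
  m <- mean(values)
  if (m <= 0) stop("undefined statistic: mean <= 0")
  100 * stats::sd(values) / m
}

#' Percent of events above a positivity threshold
#'
#' @param values Numeric vector of linear intensities.
#' @param threshold Linear threshold (> 0); events strictly above it count
#'   as positive.
#' @return Percent positive in `[0, 100]`.
#' @export
percent_positive <- function(values, threshold) {
  stopifnot(length(values) >= 1L, is.numeric(threshold), threshold > 0)
  100 * sum(values > threshold) / length(values)
}

#' Positivity threshold from an uncoupled-bead control
#'
#' The default positivity threshold is the 99th percentile of the control
#' acquisition (beads not coupled with conjugate) on the same channel.
#'
#' @param control An [event_table()] acquired on uncoupled beads.
#' @param channel Channel name.
#' @param percentile Percentile in (0, 1); default 0.99.
#' @param gate Optional `gate_result` restricting the control events.
#' @return Linear threshold.
#' @export
positivity_threshold <- function(control, channel, percentile = 0.99,
                                 gate = NULL) {
  stopifnot(percentile > 0, percentile < 1)
  v <- channel_values(control, channel,
                      events = if (!is.null(gate)) gate$kept)
  as.numeric(stats::quantile(v, percentile, names = FALSE))
}

#' All three histogram statistics for one gated population
#'
#' Computes geometric mean (FI), CV% and percent positive for a channel over
#' the gated events, together with the arithmetic mean and SD they derive
#' from. With a single event the CV is undefined and returned as `NA` with
#' `cv_defined = FALSE`.
#'
#' @param table An [event_table()].
#' @param gate A `gate_result`, or `NULL` to use all events.
#' @param channel Channel name (default `"FL2"`, the PE reporter).
#' @param threshold Explicit linear positivity threshold; overrides
#'   `control`.
#' @param control Optional uncoupled-bead control [event_table()]; its
#'   `percentile` quantile on `channel` becomes the threshold.
#' @param percentile Control percentile for the threshold; default 0.99.
#' @return A `channel_stats` object: channel, `n`, `geo_mean`,
#'   `arith_mean`, `sd`, `cv_percent`, `pct_positive`, `threshold`, plus
#'   `meta` carried over from the table.
#' @export
population_stats <- function(table, gate = NULL, channel = "FL2",
                             threshold = NULL, control = NULL,
                             percentile = 0.99) {
  stopifnot(inherits(table, "event_table"))
  idx <- if (!is.null(gate)) gate$kept else seq_len(n_events(table))
  if (length(idx) < 1L) stop("empty gate")
  v <- channel_values(table, channel, idx)
  if (is.null(threshold) && !is.null(control)) {
    threshold <- positivity_threshold(control, channel, percentile)
  }
  gm <- geometric_mean(v)
  cv_ok <- length(v) >= 2L && mean(v) > 0
  structure(
    list(channel = channel,
         n = length(v),
         geo_mean = gm,
         arith_mean = mean(v),
         sd = if (length(v) >= 2L) stats::sd(v) else NA_real_,
         cv_percent = if (cv_ok) cv_percent(v) else NA_real_,
         cv_defined = cv_ok,
         pct_positive = if (!is.null(threshold)) {
           percent_positive(v, threshold)
         } else NA_real_,
         threshold = if (is.null(threshold)) NA_real_ else threshold,
         meta = table$meta),
    class = "channel_stats"
  )
}

#' @export
print.channel_stats <- function(x, ...) {
  cat(sprintf(
    "channel_stats [%s]: n=%d  FI (geo mean)=%.4g  CV%%=%.4g  %%positive=%s\n",
    x$channel, x$n, x$geo_mean,
    if (x$cv_defined) x$cv_percent else NA,
    if (is.na(x$pct_positive)) "NA" else sprintf("%.2f", x$pct_positive)))
  invisible(x)
}

#' Flatten channel_stats objects into a tidy data frame
#'
#' One row per statistic set, suitable for CSV export (one row per sample x
#' channel).
#'
#' @param stats_list A list of `channel_stats` objects.
#' @return A data frame.
#' @export
stats_to_df <- function(stats_list) {
  if (inherits(stats_list, "channel_stats")) stats_list <- list(stats_list)
  do.call(rbind, lapply(stats_list, function(s) {
    data.frame(
      sample_id = if (!is.null(s$meta$sample_id)) s$meta$sample_id
                  else NA_character_,
      channel = s$channel, n = s$n, geo_mean = s$geo_mean,
      arith_mean = s$arith_mean, sd = s$sd, cv_percent = s$cv_percent,
      pct_positive = s$pct_positive, threshold = s$threshold,
      stringsAsFactors = FALSE
    )
  }))
}
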