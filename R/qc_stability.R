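#' Build a conjugate stability series
#'
#' Assembles the time-ordered FI (geometric mean) record of one conjugate
#' and derives the two headline stability numbers: `delta_fi = FI(first) -
#' FI(last)` and `pct_decrease = 100 * delta_fi / FI(first)`. Timepoints
#' flagged as instrument drift in the standards report are recorded in
#' `excluded_timepoints` and, by default, first/last are taken from the
#' non-excluded timepoints only (set `use_full_span = TRUE` in the config to
#' keep the raw span). MESF values are attached only where in range; a
#' conjugate brighter than the top standard stays in FI-based statements but
#' never enters MESF-based ones.
#'
#' @param conjugate_id Conjugate identifier.
#' @param timepoints Ordered numeric timepoints (months).
#' @param fi FI (geometric mean, linear units) per timepoint.
#' @param mesf Optional `mesf_value` rows (or numeric vector) per timepoint.
#' @param mesf_flags Optional character range flags per timepoint (used when
#'   `mesf` is a plain numeric vector).
#' @param drift_report Optional `drift_report` from [monitor_standards()];
#'   its flagged timepoints become `excluded_timepoints`.
#' @param config A [qc_config()].
#' @return A `stability_series`.
#' @export
build_stability_series <- function(conjugate_id, timepoints, fi,
                                   mesf = NULL, mesf_flags = NULL,
                                   drift_report = NULL,
                                   config = qc_config()) {
  stopifnot(length(timepoints) >= 2L, length(fi) == length(timepoints),
            !is.unsorted(timepoints), all(fi > 0))
  timepoints <- unname(timepoints)
  fi <- unname(fi)
  if (is.numeric(mesf)) mesf <- unname(mesf)
  if (is.character(mesf_flags)) mesf_flags <- unname(mesf_flags)
  if (inherits(mesf, "mesf_value")) {
    mesf_flags <- mesf$range_flag
    mesf <- mesf$mesf
  }
  if (!is.null(mesf)) {
    stopifnot(length(mesf) == length(timepoints))
    if (is.null(mesf_flags)) mesf_flags <- rep("in_range", length(mesf))
  }
  excluded <- numeric(0)
  if (!is.null(drift_report)) {
    excluded <- intersect(drift_report$flagged, timepoints)
  }
  usable <- if (config$use_full_span) timepoints
            else setdiff(timepoints, excluded)
  if (length(usable) < 2L) {
    stop("series error: fewer than 2 non-excluded timepoints")
  }
  i_first <- match(min(usable), timepoints)
  i_last <- match(max(usable), timepoints)
  delta_fi <- fi[i_first] - fi[i_last]
  mesf_usable <- if (!is.null(mesf)) {
    ifelse(mesf_flags == "in_range", mesf, NA_real_)
  } else NULL
  structure(
    list(conjugate_id = conjugate_id,
         timepoints = timepoints,
         fi = fi,
         mesf = mesf_usable,
         mesf_flags = mesf_flags,
         delta_fi = delta_fi,
         pct_decrease = 100 * delta_fi / fi[i_first],
         first_timepoint = timepoints[i_first],
         last_timepoint = timepoints[i_last],
         initial_fi = fi[i_first],
         final_fi = fi[i_last],
         excluded_timepoints = excluded,
         fi_only = !is.null(mesf_flags) && all(mesf_flags != "in_range")),
    class = "stability_series"
  )
}

#' @export
print.stability_series <- function(x, ...) {
  cat(sprintf(
    "stability_series [%s]: months %g..%g, FI %.4g -> %.4g, dFI = %.4g (%.1f%% decrease)\n",
    x$conjugate_id, x$first_timepoint, x$last_timepoint, x$initial_fi,
    x$final_fi, x$delta_fi, x$pct_decrease))
  if (length(x$excluded_timepoints)) {
    cat("  drift-excluded months:",
        paste(x$excluded_timepoints, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Rank conjugates by stability and by brightness
#'
#' Stability is ranked by ascending delta-FI (a smaller initial-minus-final
#' drop means a more stable conjugate); brightness is ranked separately by
#' descending initial FI — the two orderings are routinely different (a
#' bright conjugate can be the least stable), so both are reported. Series
#' that never produced an in-range MESF value carry an `fi_only` provenance
#' tag. Mismatched timepoint spans attach a comparability warning but do
#' not suppress the ranking.
#'
#' @param series_set List of `stability_series`.
#' @return A `qc_verdict` with rule `stability_rank`; `details$ranking` is a
#'   data frame ordered by stability.
#' @export
rank_stability <- function(series_set) {
  stopifnot(length(series_set) >= 2L)
  df <- do.call(rbind, lapply(series_set, function(s) {
    data.frame(conjugate_id = s$conjugate_id, delta_fi = s$delta_fi,
               pct_decrease = s$pct_decrease, initial_fi = s$initial_fi,
               span_first = s$first_timepoint, span_last = s$last_timepoint,
               fi_only = isTRUE(s$fi_only), stringsAsFactors = FALSE)
  }))
  warn <- NULL
  if (length(unique(df$span_first)) > 1L ||
      length(unique(df$span_last)) > 1L) {
    warn <- "timepoint spans differ across conjugates; ranking is indicative"
  }
  df$stability_rank <- rank(df$delta_fi, ties.method = "min")
  df$brightness_rank <- rank(-df$initial_fi, ties.method = "min")
  ord <- order(df$delta_fi, df$conjugate_id)
  df <- df[ord, , drop = FALSE]
  tie <- anyDuplicated(df$delta_fi) > 0L
  verdict <- if (tie && length(unique(df$delta_fi)) == 1L) {
    "tie: all conjugates equally stable by delta-FI"
  } else {
    paste0("most stable: ", df$conjugate_id[[1]],
           " (stability order ", paste(df$conjugate_id, collapse = " < "),
           "); brightest: ",
           df$conjugate_id[which.min(df$brightness_rank)])
  }
  qc_verdict(
    subject = paste(df$conjugate_id, collapse = ","),
    rule = "stability_rank",
    verdict = verdict,
    evidence = stats::setNames(as.list(df$delta_fi),
                               paste0("delta_fi_", df$conjugate_id)),
    details = list(ranking = df, comparability_warning = warn)
  )
}

#' Attribute fluorescence decline to instrument or conjugate
#'
#' The attribution logic: a decline that coincides with a flagged standards
#' drift episode (all standards moving together) is an instrument
#' sensitivity change; a decline while the standards stay flat is a true
#' conjugate change. Each timepoint with FI below baseline beyond
#' `config$drift_tolerance` is labelled `"instrument"` when the standards
#' report flags it, `"conjugate"` otherwise; timepoints within tolerance are
#' `"stable"`. The overall verdict is "true conjugate decrease" only when
#' the first-vs-last decline persists using non-flagged timepoints alone.
#'
#' @param series A `stability_series`.
#' @param drift_report A `drift_report` covering the same timepoints.
#' @param config A [qc_config()].
#' @return A `qc_verdict` with rule `decline_attribution`;
#'   `details$per_timepoint` holds the per-month labels.
#' @export
attribute_decline <- function(series, drift_report, config = qc_config()) {
  stopifnot(inherits(series, "stability_series"),
            inherits(drift_report, "drift_report"))
  overlap <- intersect(series$timepoints, drift_report$timepoints)
  if (length(overlap) < 2L) {
    stop("attribution error: no overlapping timepoints with standards")
  }
  tol <- config$drift_tolerance
  base <- series$fi[[1]]
  rel <- series$fi / base - 1
  label <- rep("stable", length(series$timepoints))
  declining <- rel < -tol
  flagged <- series$timepoints %in% drift_report$flagged
  label[declining & flagged] <- "instrument"
  label[declining & !flagged] <- "conjugate"
  label[!declining & flagged] <- "instrument"
  usable <- !flagged
  fi_u <- series$fi[usable]
  pct <- 100 * (fi_u[[1]] - fi_u[[length(fi_u)]]) / fi_u[[1]]
  verdict <- if (pct > 100 * tol) "true conjugate decrease"
             else "no true decrease"
  qc_verdict(
    subject = series$conjugate_id,
    rule = "decline_attribution",
    verdict = verdict,
    evidence = list(pct_decrease_nonflagged = pct,
                    n_instrument_timepoints = sum(label == "instrument"),
                    n_conjugate_timepoints = sum(label == "conjugate")),
    details = list(per_timepoint = data.frame(
      timepoint = series$timepoints, fi = series$fi,
      rel_change = rel, attribution = label, stringsAsFactors = FALSE))
  )
}
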