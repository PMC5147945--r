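#' Study-level QC configuration
#'
#' Central defaults for the decision layer. `alpha` is the per-comparison
#' significance level; no multiple-testing correction is applied by default
#' (`holm = TRUE` switches it on for the group comparisons that return
#' several p-values).
#'
#' @param alpha Significance level in (0, 1); default 0.05.
#' @param min_events Minimum gated events per acquisition; default 2000.
#' @param drift_tolerance Relative tolerance for standards drift; default
#'   0.10.
#' @param positivity_percentile Control percentile defining the positivity
#'   threshold; default 0.99.
#' @param fade_threshold PE retained fraction below which the fluorochrome
#'   is considered faded; default 0.50.
#' @param retention_threshold FITC retained fraction at or above which the
#'   antibody is considered still coupled; default 0.75.
#' @param k_mad Scatter-gate spread multiplier; default 4.
#' @param use_full_span Compute delta-FI from the raw first/last timepoints
#'   even when some are drift-flagged; default `FALSE` (use first/last
#'   non-excluded).
#' @param pooled_t Use the pooled-variance t-test instead of Welch.
#' @param holm Apply Holm correction where several p-values are produced.
#' @return A `qc_config` list.
#' @export
qc_config <- function(alpha = 0.05, min_events = 2000L,
                      drift_tolerance = 0.10, positivity_percentile = 0.99,
                      fade_threshold = 0.50, retention_threshold = 0.75,
                      k_mad = 4, use_full_span = FALSE, pooled_t = FALSE,
                      holm = FALSE) {
  stopifnot(alpha > 0, alpha < 1, min_events >= 1, drift_tolerance > 0,
            positivity_percentile > 0, positivity_percentile < 1,
            fade_threshold > 0, retention_threshold > 0, k_mad > 0)
  structure(
    list(alpha = alpha, min_events = as.integer(min_events),
         drift_tolerance = drift_tolerance,
         positivity_percentile = positivity_percentile,
         fade_threshold = fade_threshold,
         retention_threshold = retention_threshold,
         k_mad = k_mad, use_full_span = use_full_span,
         pooled_t = pooled_t, holm = holm),
    class = "qc_config"
  )
}

#' Construct a QC verdict
#'
#' A categorical decision with its supporting numbers attached; every
#' verdict carries at least one evidence number, and p-values, where
#' present, lie in (0, 1].
#'
#' @param subject Conjugate/sample id the verdict concerns.
#' @param rule One of `concentration_choice`, `homogeneity`,
#'   `stability_rank`, `decline_attribution`, `stain_integrity`.
#' @param verdict Categorical outcome string.
#' @param evidence Named numeric vector/list of supporting numbers.
#' @param p_values Optional named numeric p-values.
#' @param details Optional free-form extras (data frames etc.).
#' @return A `qc_verdict`.
#' @export
qc_verdict <- function(subject, rule, verdict, evidence, p_values = NULL,
                       details = NULL) {
  rule <- match.arg(rule, c("concentration_choice", "homogeneity",
                            "stability_rank", "decline_attribution",
                            "stain_integrity"))
  ev <- unlist(evidence)
  if (length(ev) < 1L) stop("verdict requires at least one evidence number")
  if (!is.null(p_values)) {
    pv <- unlist(p_values)
    if (any(!is.na(pv) & (pv <= 0 | pv > 1))) {
      stop("p-values must lie in (0, 1]")
    }
  }
  structure(
    list(subject = subject, rule = rule, verdict = verdict,
         evidence = evidence, p_values = p_values, details = details),
    class = "qc_verdict"
  )
}

#' @export
print.qc_verdict <- function(x, ...) {
  cat(sprintf("qc_verdict [%s] %s: %s\n", x$rule, x$subject, x$verdict))
  ev <- unlist(x$evidence)
  cat("  evidence:",
      paste(sprintf("%s=%.4g", names(ev), ev), collapse = ", "), "\n")
  if (!is.null(x$p_values)) {
    pv <- unlist(x$p_values)
    cat("  p-values:",
        paste(sprintf("%s=%.3g", names(pv), pv), collapse = ", "), "\n")
  }
  invisible(x)
}
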