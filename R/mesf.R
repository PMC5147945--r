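#' Define an MESF standard set
#'
#' A quantitative-cytometry kit provides five bead populations: a certified
#' blank plus four levels of increasing fluorochrome load. Each non-blank
#' population carries an assigned MESF value (molecules of equivalent
#' soluble fluorochrome); the measured geometric means come from the
#' concurrently acquired standards tube.
#'
#' @param labels Character vector of population labels.
#' @param assigned_mesf Assigned MESF per population (blank smallest).
#' @param geo_mean Measured geometric mean (linear intensity) per
#'   population.
#' @param blank_label Which label is the certified blank.
#' @return An `mesf_standard_set`.
#' @export
mesf_standard_set <- function(labels, assigned_mesf, geo_mean,
                              blank_label = labels[[1]]) {
  stopifnot(length(labels) == length(assigned_mesf),
            length(labels) == length(geo_mean))
  if (sum(labels == blank_label) != 1L) {
    stop("exactly one blank population required")
  }
  blank <- labels == blank_label
  if (any(assigned_mesf[!blank] <= assigned_mesf[blank])) {
    stop("blank's assigned MESF must be the smallest")
  }
  nb_ord <- order(assigned_mesf[!blank])
  mesf_nb <- assigned_mesf[!blank][nb_ord]
  gm_nb <- geo_mean[!blank][nb_ord]
  if (any(diff(mesf_nb) <= 0) || any(diff(gm_nb) <= 0)) {
    stop("invariant violation: non-blank standards must be strictly ",
         "increasing in both assigned MESF and geometric mean")
  }
  structure(
    list(populations = data.frame(label = labels,
                                  assigned_mesf = assigned_mesf,
                                  geo_mean = geo_mean,
                                  stringsAsFactors = FALSE),
         blank_label = blank_label),
    class = "mesf_standard_set"
  )
}

non_blank <- function(standards) {
  pops <- standards$populations
  pops[pops$label != standards$blank_label, , drop = FALSE]
}

#' Fit the MESF calibration curve
#'
#' Ordinary least squares of `log10(assigned MESF)` on `log10(geometric
#' mean)` over the non-blank standards — the standard quantitative-cytometry
#' model on a log-amplified instrument. The blank is excluded from the fit
#' and defines the lower detection limit (the model's MESF at the blank's
#' geometric mean); the brightest standard's geometric mean is the upper
#' limit beyond which samples are non-evaluable.
#'
#' @param standards An [mesf_standard_set()] with at least 2 non-blank
#'   populations with distinct geometric means.
#' @param fit_date Optional acquisition timestamp carried on the model.
#' @return A `calibration_model`: `slope`, `intercept`, `r_squared`,
#'   `lower_limit_mesf`, `upper_limit_gm`, `blank_gm`, `fit_date`.
#' @export
fit_calibration <- function(standards, fit_date = NULL) {
  stopifnot(inherits(standards, "mesf_standard_set"))
  nb <- non_blank(standards)
  if (nrow(nb) < 2L || length(unique(nb$geo_mean)) < 2L) {
    stop("calibration error: need >= 2 non-blank standards with distinct ",
         "geometric means")
  }
  x <- log10(nb$geo_mean)
  y <- log10(nb$assigned_mesf)
  fit <- stats::lm(y ~ x)
  slope <- unname(coef(fit)[2])
  intercept <- unname(coef(fit)[1])
  if (slope <= 0) stop("calibration error: fitted slope is not positive")
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 1
  blank_gm <- standards$populations$geo_mean[
    standards$populations$label == standards$blank_label]
  structure(
    list(slope = slope, intercept = intercept, r_squared = r2,
         lower_limit_mesf = 10^(slope * log10(blank_gm) + intercept),
         upper_limit_gm = max(nb$geo_mean),
         blank_gm = blank_gm,
         fit_date = fit_date),
    class = "calibration_model"
  )
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf(
    "calibration_model: log10(MESF) = %.4f * log10(GM) + %.4f  (R^2 = %.4f)\n",
    x$slope, x$intercept, x$r_squared))
  cat(sprintf("  range: lower limit %.4g MESF (blank), upper limit GM %.4g\n",
              x$lower_limit_mesf, x$upper_limit_gm))
  invisible(x)
}

#' Assign MESF values to samples
#'
#' `MESF = 10^(slope * log10(GM) + intercept)`. Samples brighter than the
#' top standard are extrapolated numerically but hard-flagged
#' `above_range` (non-evaluable by quantitative cytometry — such conjugates
#' fall back to raw FI for stability statements); samples dimmer than the
#' blank are flagged `below_blank`.
#'
#' @param model A `calibration_model` from [fit_calibration()].
#' @param sample_gm Positive geometric mean(s) of the sample(s).
#' @param sample_id Optional id(s), recycled.
#' @return A data frame of class `mesf_value` with columns `sample_id`,
#'   `geo_mean`, `mesf`, `range_flag`.
#' @export
assign_mesf <- function(model, sample_gm, sample_id = NULL) {
  stopifnot(inherits(model, "calibration_model"), all(sample_gm > 0))
  mesf <- 10^(model$slope * log10(sample_gm) + model$intercept)
  flag <- rep("in_range", length(sample_gm))
  flag[sample_gm < model$blank_gm] <- "below_blank"
  flag[sample_gm > model$upper_limit_gm] <- "above_range"
  out <- data.frame(
    sample_id = if (is.null(sample_id)) {
      as.character(seq_along(sample_gm))
    } else rep_len(as.character(sample_id), length(sample_gm)),
    geo_mean = sample_gm, mesf = mesf, range_flag = flag,
    stringsAsFactors = FALSE
  )
  class(out) <- c("mesf_value", class(out))
  out
}

#' Monitor calibration standards across timepoints
#'
#' Computes, for every timepoint and non-blank standard, the relative
#' deviation of its geometric mean from baseline, `(GM_t - GM_0)/GM_0`. A
#' timepoint is flagged "instrument drift" when ALL non-blank standards
#' deviate beyond `tolerance` in the SAME direction — coupled movement of
#' independent stable standards is the signature of an instrument
#' sensitivity change, not of the standards themselves. A lone standard
#' exceeding tolerance raises an inconsistent-standard warning instead.
#' First-vs-last absolute GM differences per standard are also reported.
#'
#' @param sets List of [mesf_standard_set()] objects, time-ordered, with
#'   identical labels.
#' @param timepoints Numeric timepoints (e.g. months), same length.
#' @param tolerance Relative deviation tolerance; default 0.10.
#' @return A `drift_report`: `deviations` (long data frame), `flagged`
#'   (timepoints attributed to instrument drift), `inconsistent`
#'   (timepoints with partial excursions), `first_vs_last` (named absolute
#'   GM differences), `tolerance`.
#' @export
monitor_standards <- function(sets, timepoints, tolerance = 0.10) {
  stopifnot(length(sets) == length(timepoints), length(sets) >= 2L)
  labels0 <- sets[[1]]$populations$label
  for (s in sets) {
    if (!identical(s$populations$label, labels0)) {
      stop("series error: standard labels differ across timepoints")
    }
  }
  nb0 <- non_blank(sets[[1]])
  gm_mat <- vapply(sets, function(s) non_blank(s)$geo_mean,
                   numeric(nrow(nb0)))
  gm_mat <- matrix(gm_mat, nrow = nrow(nb0))  # standards x timepoints
  dev <- sweep(gm_mat, 1, gm_mat[, 1], "/") - 1
  flagged <- inconsistent <- numeric(0)
  for (j in seq_along(timepoints)[-1]) {
    beyond <- abs(dev[, j]) > tolerance
    same_dir <- length(unique(sign(dev[beyond, j]))) <= 1L
    if (all(beyond) && same_dir) {
      flagged <- c(flagged, timepoints[j])
    } else if (any(beyond)) {
      inconsistent <- c(inconsistent, timepoints[j])
      warning("inconsistent standard excursion at timepoint ",
              timepoints[j], call. = FALSE)
    }
  }
  deviations <- data.frame(
    timepoint = rep(timepoints, each = nrow(nb0)),
    label = rep(nb0$label, times = length(timepoints)),
    geo_mean = as.vector(gm_mat),
    deviation = as.vector(dev),
    stringsAsFactors = FALSE
  )
  structure(
    list(deviations = deviations,
         flagged = flagged,
         inconsistent = inconsistent,
         first_vs_last = stats::setNames(
           abs(gm_mat[, ncol(gm_mat)] - gm_mat[, 1]), nb0$label),
         timepoints = timepoints,
         tolerance = tolerance),
    class = "drift_report"
  )
}

#' @export
print.drift_report <- function(x, ...) {
  cat("drift_report over timepoints",
      paste(range(x$timepoints), collapse = ".."), "\n")
  cat("  instrument-drift flagged:",
      if (length(x$flagged)) paste(x$flagged, collapse = ", ") else "none",
      "\n")
  cat("  first-vs-last |dGM|:",
      paste(sprintf("%s=%.3g", names(x$first_vs_last), x$first_vs_last),
            collapse = ", "), "\n")
  invisible(x)
}
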