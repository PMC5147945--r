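#' Analyze a full stability study
#'
#' End-to-end orchestration of one 18-month-style study: per month, every
#' conjugate tube is scatter-gated, checked against the minimum-event rule
#' and reduced to FL2 [population_stats()]; the concurrent standards tube is
#' measured and the calibration refitted from it (settings are assumed
#' constant, but the calibration always comes from the same-day standards
#' acquisition); MESF values are assigned with range flags. Standards are
#' then monitored across months for instrument drift, stability series are
#' built per conjugate with drift-flagged months excluded, conjugates are
#' ranked, and each series' decline is attributed to instrument or
#' conjugate.
#'
#' @param study A `stability_study` from [simulate_stability_study()], or a
#'   structurally identical list built from real acquisitions.
#' @param config A [qc_config()].
#' @return List with `stats` (tidy per-acquisition data frame), `series`
#'   (named list of `stability_series`), `drift_report`, `calibrations`
#'   (per month), `rank` (stability-rank `qc_verdict`), `attributions`
#'   (per-conjugate `qc_verdict`s), `min_event_failures`.
#' @export
analyze_stability_study <- function(study, config = qc_config()) {
  months <- study$months
  conj_ids <- names(study$acquisitions[[1]]$conjugates)
  standard_sets <- vector("list", length(months))
  calibrations <- vector("list", length(months))
  fi <- matrix(NA_real_, nrow = length(conj_ids), ncol = length(months),
               dimnames = list(conj_ids, paste0("m", months)))
  mesf <- fi
  flags <- matrix(NA_character_, nrow = length(conj_ids),
                  ncol = length(months),
                  dimnames = dimnames(fi))
  min_event_failures <- character(0)
  rows <- list()
  for (j in seq_along(months)) {
    acq <- study$acquisitions[[j]]
    standard_sets[[j]] <- measure_standard_tube(acq$standard_tube)
    calibrations[[j]] <- fit_calibration(standard_sets[[j]])
    for (id in conj_ids) {
      tab <- acq$conjugates[[id]]
      gate <- gate_singlets(tab, k = config$k_mad)
      if (!check_min_events(gate, config$min_events)) {
        min_event_failures <- c(
          min_event_failures, sprintf("%s_m%d", id, acq$month))
      }
      st <- population_stats(tab, gate, channel = "FL2")
      mv <- assign_mesf(calibrations[[j]], st$geo_mean, sample_id = id)
      fi[id, j] <- st$geo_mean
      mesf[id, j] <- mv$mesf
      flags[id, j] <- mv$range_flag
      rows[[length(rows) + 1L]] <- data.frame(
        conjugate = id, month = acq$month, n_gated = gate$n_kept,
        geo_mean = st$geo_mean, cv_percent = st$cv_percent,
        mesf = mv$mesf, range_flag = mv$range_flag,
        stringsAsFactors = FALSE)
    }
  }
  drift <- monitor_standards(standard_sets, months,
                             tolerance = config$drift_tolerance)
  series <- lapply(conj_ids, function(id) {
    build_stability_series(id, months, fi[id, ], mesf = mesf[id, ],
                           mesf_flags = flags[id, ], drift_report = drift,
                           config = config)
  })
  names(series) <- conj_ids
  list(
    stats = do.call(rbind, rows),
    series = series,
    drift_report = drift,
    calibrations = calibrations,
    rank = if (length(series) >= 2L) rank_stability(series) else NULL,
    attributions = lapply(series, attribute_decline, drift_report = drift,
                          config = config),
    min_event_failures = min_event_failures
  )
}

#' Read a study configuration file
#'
#' YAML (or JSON) study configuration: channel mapping, thresholds, seeds,
#' standards file, acquisitions. Only light validation is applied here; the
#' individual operations validate what they consume.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return Named list.
#' @export
read_study_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}

#' Export QC verdicts as JSON
#'
#' @param verdicts A `qc_verdict` or list of them.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_verdicts <- function(verdicts, path) {
  if (inherits(verdicts, "qc_verdict")) verdicts <- list(verdicts)
  out <- lapply(verdicts, function(v) {
    list(subject = v$subject, rule = v$rule, verdict = v$verdict,
         evidence = v$evidence, p_values = v$p_values)
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Plot stability series (FI vs month)
#'
#' One line per conjugate on a log10 FI axis, with drift-excluded months
#' marked.
#'
#' @param series_set List of `stability_series`.
#' @return A ggplot object.
#' @export
plot_stability <- function(series_set) {
  if (inherits(series_set, "stability_series")) series_set <- list(series_set)
  df <- do.call(rbind, lapply(series_set, function(s) {
    data.frame(conjugate = s$conjugate_id, month = s$timepoints, fi = s$fi,
               excluded = s$timepoints %in% s$excluded_timepoints)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = month, y = fi,
                                   colour = conjugate)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(shape = excluded)) +
    ggplot2::scale_y_log10() +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 1)) +
    ggplot2::labs(x = "month", y = "FI (geometric mean)",
                  shape = "drift-excluded") +
    ggplot2::theme_minimal()
}

#' Overlay first-vs-last fluorescence histograms
#'
#' Mirrors the classic stability readout: the reporter-channel histogram at
#' the first and last timepoint on a log-scale axis spanning 10^0-10^4.
#'
#' @param first,last [event_table()]s of the first and last acquisition.
#' @param channel Channel to plot; default `"FL2"`.
#' @return A ggplot object.
#' @export
plot_fi_histograms <- function(first, last, channel = "FL2") {
  df <- rbind(
    data.frame(value = channel_values(first, channel), acquisition = "first"),
    data.frame(value = channel_values(last, channel), acquisition = "last")
  )
  df <- df[df$value > 0, , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = value, fill = acquisition)) +
    ggplot2::geom_histogram(bins = 128, alpha = 0.6,
                            position = "identity") +
    ggplot2::scale_x_log10(limits = c(1, 1e4)) +
    ggplot2::labs(x = paste(channel, "intensity"), y = "count") +
    ggplot2::theme_minimal()
}
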