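#' Canonical flow-cytometry channels
#'
#' The five channels the pipeline works with, in FACSCalibur terms: forward
#' and side scatter, FITC (secondary stain), PE (reporter) and the bead-code
#' classification channel.
#'
#' @export
CANONICAL_CHANNELS <- c("FSC", "SSC", "FL1", "FL2", "FL4")

#' Construct an event table
#'
#' An `event_table` holds per-event channel intensities on a LINEAR relative
#' fluorescence scale (log-amplified channels are decoded once, at read
#' time), plus acquisition metadata and a per-channel amplifier descriptor.
#'
#' @param events Numeric matrix, rows = events, named columns = channels
#'   (typically `FSC`, `SSC`, `FL1`, `FL2`, `FL4`). Values must be finite
#'   and non-negative.
#' @param meta Named list of acquisition metadata (sample id, conjugate id,
#'   lot, concentration, timepoint in months, storage condition,
#'   acquisition date). Free-form; missing entries are allowed.
#' @param channel_spec Data frame with columns `channel`, `decades`,
#'   `max_channel`, `linear` describing the amplifier each channel was
#'   acquired with. Defaults to linear for every channel.
#'
#' @return An object of class `event_table`.
#' @export
#' @examples
#' ev <- matrix(c(500, 300, 2, 800, 120), nrow = 1,
#'              dimnames = list(NULL, c("FSC", "SSC", "FL1", "FL2", "FL4")))
#' event_table(ev, meta = list(sample_id = "A1-m0"))
event_table <- function(events, meta = list(), channel_spec = NULL) {
  if (!is.matrix(events) || !is.numeric(events)) {
    stop("`events` must be a numeric matrix")
  }
  if (is.null(colnames(events)) || any(!nzchar(colnames(events)))) {
    stop("`events` must have named channel columns")
  }
  if (nrow(events) < 1L) stop("event count must be >= 1")
  if (any(!is.finite(events))) stop("all intensities must be finite")
  if (any(events < 0)) stop("all intensities must be >= 0")
  if (is.null(channel_spec)) {
    channel_spec <- data.frame(
      channel = colnames(events),
      decades = NA_real_,
      max_channel = NA_integer_,
      linear = TRUE,
      stringsAsFactors = FALSE
    )
  }
  structure(
    list(events = events, meta = as.list(meta), channel_spec = channel_spec),
    class = "event_table"
  )
}

#' @export
print.event_table <- function(x, ...) {
  cat("event_table:", nrow(x$events), "events x",
      ncol(x$events), "channels (", paste(colnames(x$events), collapse = ", "),
      ")\n")
  if (length(x$meta)) {
    keep <- intersect(c("sample_id", "conjugate", "timepoint"), names(x$meta))
    for (k in keep) cat(" ", k, "=", as.character(x$meta[[k]]), "\n")
  }
  invisible(x)
}

#' Number of events in an event table
#' @param table An `event_table`.
#' @return Integer event count.
#' @export
n_events <- function(table) {
  stopifnot(inherits(table, "event_table"))
  nrow(table$events)
}

#' Extract one channel from an event table
#'
#' @param table An `event_table`.
#' @param channel Channel name (e.g. `"FL2"`).
#' @param events Optional integer index of events to keep (e.g. a gate's
#'   `kept` set); default all.
#' @return Numeric vector of linear intensities.
#' @export
channel_values <- function(table, channel, events = NULL) {
  stopifnot(inherits(table, "event_table"))
  if (!channel %in% colnames(table$events)) {
    stop("channel mapping error: channel '", channel, "' not present")
  }
  v <- table$events[, channel]
  if (!is.null(events)) v <- v[events]
  v
}

#' Subset an event table by event index
#'
#' @param table An `event_table`.
#' @param events Integer indices of events to keep.
#' @return A new `event_table` with the same metadata.
#' @export
subset_events <- function(table, events) {
  stopifnot(inherits(table, "event_table"))
  if (length(events) < 1L) stop("empty gate: no events selected")
  event_table(table$events[events, , drop = FALSE], meta = table$meta,
              channel_spec = table$channel_spec)
}

#' Decode a log-amplified channel value to linear relative intensity
#'
#' Standard flow-cytometer log-amplifier transform: a stored channel number
#' `x` on a `decades`-decade scale of `max_channel` channels maps to
#' `10^(decades * x / max_channel)`. Channel 0 maps to 1 and full scale to
#' `10^decades`; the transform is strictly monotone.
#'
#' @param stored Stored channel value(s), `0 <= stored <= max_channel`.
#' @param decades Number of log decades of the amplifier (> 0), e.g. 4.
#' @param max_channel Resolution of the scale (e.g. 1024).
#' @return Linear relative intensity, same length as `stored`.
#' @export
#' @examples
#' decode_log_channel(512, decades = 4, max_channel = 1024)  # 100
decode_log_channel <- function(stored, decades, max_channel) {
  if (!is.numeric(decades) || decades <= 0) stop("`decades` must be > 0")
  if (!is.numeric(max_channel) || max_channel <= 0) {
    stop("`max_channel` must be > 0")
  }
  if (any(stored < 0 | stored > max_channel)) {
    stop("range error: stored value outside [0, ", max_channel, "]")
  }
  10^(decades * stored / max_channel)
}
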