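#' Default channel-name mapping (FACSCalibur height parameters)
#'
#' Maps the canonical channel names used throughout the package to the
#' `$PnN` names found in list-mode files. Instruments differ in naming, so
#' the mapping is configuration, not code; pass your own named vector to
#' [read_events()] when needed. Canonical names themselves are always
#' accepted.
#'
#' @return Named character vector, names = canonical channels, values =
#'   instrument `$PnN` names.
#' @export
default_channel_map <- function() {
  c(FSC = "FSC-H", SSC = "SSC-H", FL1 = "FL1-H", FL2 = "FL2-H",
    FL4 = "FL4-H")
}

#' Read event-level list-mode data
#'
#' Reads either a standard FCS 3.0/3.1 file or the plain CSV dialect (header
#' `FSC,SSC,FL1,FL2,FL4`, one row per event). All channel values are
#' returned on the linear relative-fluorescence scale: FCS parameters with a
#' log-amplifier `$PnE` keyword (`"d,r"` with `d > 0`) are decoded via
#' [decode_log_channel()] once, at read time; linear parameters
#' (`$PnE = "0,0"`) pass through untouched.
#'
#' @param path Path to the file.
#' @param dialect `"table"` (CSV) or `"fcs"`.
#' @param channel_map Named character vector mapping canonical channel names
#'   to instrument `$PnN` names (FCS dialect only); see
#'   [default_channel_map()].
#' @param required Canonical channels that must be present; defaults to all
#'   five. A missing one raises a channel mapping error naming the channel.
#' @param meta Optional metadata list overriding anything read from the
#'   file or its sidecar.
#' @return An [event_table()].
#' @export
read_events <- function(path, dialect = c("table", "fcs"),
                        channel_map = default_channel_map(),
                        required = names(channel_map), meta = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- switch(dialect,
    table = read_events_table(path, required),
    fcs   = read_events_fcs(path, channel_map, required)
  )
  if (!is.null(meta)) tab$meta <- utils::modifyList(tab$meta, as.list(meta))
  tab
}

read_events_table <- function(path, required) {
  df <- tryCatch(
    utils::read.csv(path, check.names = FALSE),
    error = function(e) stop("format error reading '", path, "': ",
                             conditionMessage(e))
  )
  missing <- setdiff(required, colnames(df))
  if (length(missing)) {
    stop("channel mapping error: channel '", missing[[1]],
         "' not present in ", path)
  }
  meta <- list()
  sidecar <- paste0(path, ".meta.json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  }
  event_table(as.matrix(df), meta = meta)
}

#' Write event-level list-mode data
#'
#' Inverse of [read_events()]. The FCS dialect stores the table's linear
#' intensities as 32-bit floats with linear-gain keywords (`$PnE = "0,0"`);
#' values are never re-encoded to log channel numbers. The CSV dialect
#' writes one header line and one row per event; non-empty metadata goes to
#' a `<path>.meta.json` sidecar.
#'
#' @param table An [event_table()].
#' @param path Output path.
#' @param dialect `"table"` or `"fcs"`.
#' @return `path`, invisibly.
#' @export
write_events <- function(table, path, dialect = c("table", "fcs")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(table, "event_table"))
  switch(dialect,
    table = {
      utils::write.csv(as.data.frame(table$events), path, row.names = FALSE)
      if (length(table$meta)) {
        jsonlite::write_json(table$meta, paste0(path, ".meta.json"),
                             auto_unbox = TRUE, digits = NA)
      }
    },
    fcs = write_fcs(table, path)
  )
  invisible(path)
}

# ---- minimal FCS 3.0/3.1 codec -------------------------------------------
# HEADER (58 bytes) + TEXT (delimited keyword/value pairs) + DATA.
# Write path: list mode, $DATATYPE F (float32), little-endian, linear $PnE.
# Read path: $DATATYPE F/D/I, either byte order, per-parameter log decoding.

FCS_DELIM <- "|"

write_fcs <- function(table, path) {
  ev <- table$events
  p <- ncol(ev)
  n <- nrow(ev)
  kw <- c(
    "$BEGINANALYSIS" = "0", "$ENDANALYSIS" = "0",
    "$BEGINSTEXT" = "0", "$ENDSTEXT" = "0",
    "$BEGINDATA" = sprintf("%010d", 0), "$ENDDATA" = sprintf("%010d", 0),
    "$DATATYPE" = "F", "$MODE" = "L", "$BYTEORD" = "1,2,3,4",
    "$NEXTDATA" = "0", "$PAR" = as.character(p), "$TOT" = as.character(n)
  )
  for (i in seq_len(p)) {
    kw[sprintf("$P%dN", i)] <- colnames(ev)[i]
    kw[sprintf("$P%dB", i)] <- "32"
    kw[sprintf("$P%dE", i)] <- "0,0"
    kw[sprintf("$P%dR", i)] <- "262144"
  }
  if (length(table$meta)) {
    meta_json <- jsonlite::toJSON(table$meta, auto_unbox = TRUE, digits = NA)
    kw["CONJUQCMETA"] <- gsub(FCS_DELIM, "/", as.character(meta_json),
                              fixed = TRUE)
  }
  text <- build_text_segment(kw)
  text_start <- 58L
  text_end <- text_start + nchar(text) - 1L
  data_start <- text_end + 1L
  data_end <- data_start + 4L * n * p - 1L
  kw["$BEGINDATA"] <- sprintf("%010d", data_start)
  kw["$ENDDATA"] <- sprintf("%010d", data_end)
  text <- build_text_segment(kw)  # same length: placeholders are fixed-width
  header <- sprintf("FCS3.0    %8d%8d%8d%8d%8d%8d",
                    text_start, text_end, data_start, data_end, 0L, 0L)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  writeChar(text, con, eos = NULL)
  writeBin(as.numeric(t(ev)), con, size = 4L, endian = "little")
  invisible(path)
}

build_text_segment <- function(kw) {
  vals <- gsub(FCS_DELIM, "/", as.character(kw), fixed = TRUE)
  paste0(FCS_DELIM,
         paste0(names(kw), FCS_DELIM, vals, FCS_DELIM, collapse = ""))
}

read_events_fcs <- function(path, channel_map, required) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 58 || rawToChar(raw[1:3]) != "FCS") {
    stop("format error at byte offset 0: not an FCS file: ", path)
  }
  hdr <- rawToChar(raw[11:58])
  off <- suppressWarnings(as.integer(substring(
    hdr, seq(1, 41, by = 8), seq(8, 48, by = 8))))
  if (any(is.na(off[1:2]))) {
    stop("format error at byte offset 10: unreadable HEADER offsets")
  }
  text <- rawToChar(raw[(off[1] + 1L):(off[2] + 1L)])
  delim <- substr(text, 1, 1)
  parts <- strsplit(substring(text, 2), delim, fixed = TRUE)[[1]]
  if (length(parts) %% 2L == 1L) parts <- parts[-length(parts)]
  kw <- stats::setNames(as.list(parts[c(FALSE, TRUE)]),
                        toupper(parts[c(TRUE, FALSE)]))
  p <- as.integer(kw[["$PAR"]])
  tot <- as.integer(kw[["$TOT"]])
  ds <- off[3]; de <- off[4]
  if (is.na(ds) || ds == 0L) ds <- as.integer(kw[["$BEGINDATA"]])
  if (is.na(de) || de == 0L) de <- as.integer(kw[["$ENDDATA"]])
  endian <- if (identical(kw[["$BYTEORD"]], "4,3,2,1")) "big" else "little"
  dtype <- toupper(kw[["$DATATYPE"]])
  bytes <- raw[(ds + 1L):(de + 1L)]
  vals <- switch(dtype,
    F = readBin(bytes, "numeric", n = p * tot, size = 4L, endian = endian),
    D = readBin(bytes, "numeric", n = p * tot, size = 8L, endian = endian),
    I = {
      bits <- as.integer(kw[[sprintf("$P%dB", 1L)]])
      if (bits == 16L) {
        readBin(bytes, "integer", n = p * tot, size = 2L, signed = FALSE,
                endian = endian)
      } else {
        readBin(bytes, "integer", n = p * tot, size = 4L, endian = endian)
      }
    },
    stop("format error: unsupported $DATATYPE '", dtype, "'")
  )
  ev <- matrix(as.numeric(vals), ncol = p, byrow = TRUE)
  pnn <- vapply(seq_len(p), function(i) {
    nm <- kw[[sprintf("$P%dN", i)]]
    if (is.null(nm)) sprintf("P%d", i) else nm
  }, character(1))
  # map instrument names to canonical ones
  canon <- pnn
  for (cn in names(channel_map)) {
    canon[pnn == channel_map[[cn]] | pnn == cn] <- cn
  }
  colnames(ev) <- canon
  missing <- setdiff(required, canon)
  if (length(missing)) {
    stop("channel mapping error: channel '", missing[[1]],
         "' not present in ", path)
  }
  spec <- data.frame(channel = canon, decades = NA_real_,
                     max_channel = NA_integer_, linear = TRUE,
                     stringsAsFactors = FALSE)
  for (i in seq_len(p)) {
    pne <- kw[[sprintf("$P%dE", i)]]
    if (is.null(pne)) pne <- "0,0"
    fe <- as.numeric(strsplit(pne, ",", fixed = TRUE)[[1]])
    if (length(fe) >= 1 && !is.na(fe[1]) && fe[1] > 0) {
      pnr <- as.numeric(kw[[sprintf("$P%dR", i)]])
      ev[, i] <- decode_log_channel(ev[, i], decades = fe[1],
                                    max_channel = pnr)
      spec$decades[i] <- fe[1]
      spec$max_channel[i] <- as.integer(pnr)
      spec$linear[i] <- FALSE
    }
  }
  meta <- list()
  if (!is.null(kw[["CONJUQCMETA"]])) {
    meta <- tryCatch(
      jsonlite::fromJSON(kw[["CONJUQCMETA"]], simplifyVector = TRUE),
      error = function(e) list()
    )
  }
  event_table(ev, meta = meta, channel_spec = spec)
}
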