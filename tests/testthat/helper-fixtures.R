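# Shared fixture builders. Everything is generated in code; no binary files.

# Small event table with explicit channel values (recycled to n rows).
make_table <- function(n = 10, FSC = 500, SSC = 300, FL1 = 2, FL2 = 100,
                       FL4 = 500, meta = list()) {
  ev <- cbind(FSC = rep_len(FSC, n), SSC = rep_len(SSC, n),
              FL1 = rep_len(FL1, n), FL2 = rep_len(FL2, n),
              FL4 = rep_len(FL4, n))
  event_table(ev, meta = meta)
}

# A gate_result covering n_kept events (for rule-boundary tests).
fake_gate <- function(n_kept) {
  structure(list(kept = seq_len(n_kept),
                 gate_params = list(center = c(FSC = 0, SSC = 0),
                                    halfwidth = c(FSC = 1, SSC = 1),
                                    k = 4, method = "fixture"),
                 n_kept = n_kept),
            class = "gate_result")
}

# Hand-rolled FCS 3.0 writer, independent of the package's codec: 16-bit
# integer data, per-parameter $PnE so log-amplified channels can be
# exercised. `events` is an integer matrix with canonical column names;
# `pne` a character vector like c(FL2 = "4,0"), default linear.
write_raw_fcs <- function(events, path, pne = c(), pnr = 1024L) {
  p <- ncol(events); n <- nrow(events)
  kw <- c("$DATATYPE" = "I", "$MODE" = "L", "$BYTEORD" = "1,2,3,4",
          "$NEXTDATA" = "0", "$PAR" = p, "$TOT" = n)
  names_map <- c(FSC = "FSC-H", SSC = "SSC-H", FL1 = "FL1-H",
                 FL2 = "FL2-H", FL4 = "FL4-H")
  for (i in seq_len(p)) {
    ch <- colnames(events)[i]
    kw[sprintf("$P%dN", i)] <- names_map[[ch]]
    kw[sprintf("$P%dB", i)] <- "16"
    kw[sprintf("$P%dE", i)] <- if (ch %in% names(pne)) pne[[ch]] else "0,0"
    kw[sprintf("$P%dR", i)] <- as.character(pnr)
  }
  text <- paste0("/", paste0(names(kw), "/", kw, "/", collapse = ""))
  ts <- 58L
  te <- ts + nchar(text) - 1L
  ds <- te + 1L
  de <- ds + 2L * n * p - 1L
  header <- sprintf("FCS3.0    %8d%8d%8d%8d%8d%8d", ts, te, ds, de, 0L, 0L)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  writeChar(text, con, eos = NULL)
  writeBin(as.integer(t(events)), con, size = 2L, endian = "little")
  invisible(path)
}

# Lognormal population CV% closed form.
lognormal_cv <- function(sigma) 100 * sqrt(exp(sigma^2) - 1)
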