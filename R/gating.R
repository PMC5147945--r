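#' Gate the singlet bead population on FSC x SSC
#'
#' Reproducible stand-in for the manual scatter gate: an axis-aligned box
#' centred on the robust mode (median) of FSC and SSC with half-widths
#' `k * MAD` per axis. The box is re-estimated on the kept events until a
#' fixed point is reached, which makes the gate idempotent: gating the gated
#' subset returns the full subset. Doublets — aggregates sitting at about
#' twice the singlet scatter — fall outside the box and are excluded. A
#' zero-MAD axis (all events identical) gets an epsilon half-width so that
#' such events are kept and half-widths stay positive.
#'
#' @param table An [event_table()] with `FSC` and `SSC` channels.
#' @param k Spread multiplier (> 0); default 4.
#' @param max_iter Safety cap on re-estimation passes.
#' @return A `gate_result`: list with `kept` (event indices), `gate_params`
#'   (center, half-widths, `k`, method tag) and `n_kept`.
#' @export
gate_singlets <- function(table, k = 4, max_iter = 50L) {
  stopifnot(inherits(table, "event_table"), k > 0)
  fsc <- channel_values(table, "FSC")
  ssc <- channel_values(table, "SSC")
  kept <- seq_along(fsc)
  center <- halfw <- c(FSC = NA_real_, SSC = NA_real_)
  for (it in seq_len(max_iter)) {
    center <- c(FSC = stats::median(fsc[kept]), SSC = stats::median(ssc[kept]))
    halfw <- c(FSC = k * stats::mad(fsc[kept]),
               SSC = k * stats::mad(ssc[kept]))
    # degenerate axis: keep ties at the median, half-width stays > 0
    eps <- pmax(abs(center), 1) * sqrt(.Machine$double.eps)
    halfw <- pmax(halfw, eps)
    inside <- which(abs(fsc - center[["FSC"]]) <= halfw[["FSC"]] &
                    abs(ssc - center[["SSC"]]) <= halfw[["SSC"]])
    if (length(inside) == 0L) stop("empty gate: no events inside scatter box")
    if (identical(inside, kept)) break
    kept <- inside
  }
  structure(
    list(kept = kept,
         gate_params = list(center = center, halfwidth = halfw, k = k,
                            method = "median_mad_box"),
         n_kept = length(kept)),
    class = "gate_result"
  )
}

#' @export
print.gate_result <- function(x, ...) {
  cat("gate_result:", x$n_kept, "events kept;",
      sprintf("center FSC=%.1f SSC=%.1f, half-widths %.1f/%.1f (k=%g)\n",
              x$gate_params$center[["FSC"]], x$gate_params$center[["SSC"]],
              x$gate_params$halfwidth[["FSC"]],
              x$gate_params$halfwidth[["SSC"]], x$gate_params$k))
  invisible(x)
}

#' Enforce the minimum-event acquisition rule
#'
#' An acquisition is analyzable only if at least `minimum` events fall in
#' the bead gate (default 2000). Failing acquisitions are flagged for the
#' operator, never silently dropped.
#'
#' @param gate A `gate_result` from [gate_singlets()].
#' @param minimum Minimum gated events (>= 1); default 2000.
#' @return Logical: `TRUE` if the rule passes.
#' @export
check_min_events <- function(gate, minimum = 2000L) {
  stopifnot(inherits(gate, "gate_result"), minimum >= 1)
  gate$n_kept >= minimum
}

#' Classify bead codes from the FL4 channel
#'
#' Each event is labelled with the bead code whose FL4 interval contains its
#' value, or `"unassigned"` when no interval does. Intervals are
#' left-closed, right-open `[lo, hi)` and must be pairwise disjoint.
#'
#' @param table An [event_table()] with an `FL4` channel.
#' @param code_bounds Named list of length-2 numeric vectors `c(lo, hi)`,
#'   one per bead code, in linear FL4 units. `Inf` upper bounds allowed.
#' @param events Optional event index (e.g. a gate's `kept`).
#' @return A `bead_code_assignment`: list with `labels` (per-event code or
#'   `"unassigned"`), `code_bounds` and `counts` (per-label event counts).
#' @export
classify_bead_codes <- function(table, code_bounds, events = NULL) {
  stopifnot(inherits(table, "event_table"))
  if (length(code_bounds) < 1L || is.null(names(code_bounds))) {
    stop("configuration error: `code_bounds` must be a named list")
  }
  bounds <- do.call(rbind, lapply(code_bounds, function(b) {
    if (length(b) != 2L || b[1] >= b[2]) {
      stop("configuration error: each bound must be c(lo, hi) with lo < hi")
    }
    as.numeric(b)
  }))
  ord <- order(bounds[, 1])
  if (any(bounds[ord, 2][-length(ord)] > bounds[ord, 1][-1])) {
    stop("configuration error: FL4 code intervals overlap")
  }
  fl4 <- channel_values(table, "FL4", events)
  labels <- rep("unassigned", length(fl4))
  for (code in names(code_bounds)) {
    b <- code_bounds[[code]]
    labels[fl4 >= b[1] & fl4 < b[2]] <- code
  }
  counts <- table(factor(labels, levels = c(names(code_bounds), "unassigned")))
  structure(
    list(labels = labels, code_bounds = code_bounds, counts = counts),
    class = "bead_code_assignment"
  )
}

#' Derive FL4 code intervals from reference geometric means
#'
#' Bead-code populations are approximately lognormal, so cut points between
#' adjacent codes are placed at log-space midpoints (geometric means of
#' adjacent code GMs). The first interval starts at 0 and the last is
#' unbounded.
#'
#' @param code_gms Named numeric vector of per-code FL4 geometric means.
#' @return Named list of `c(lo, hi)` intervals suitable for
#'   [classify_bead_codes()].
#' @export
derive_code_bounds <- function(code_gms) {
  stopifnot(is.numeric(code_gms), all(code_gms > 0),
            !is.null(names(code_gms)))
  ord <- order(code_gms)
  gms <- code_gms[ord]
  cuts <- unname(sqrt(gms[-length(gms)] * gms[-1]))
  lo <- c(0, cuts)
  hi <- c(cuts, Inf)
  stats::setNames(lapply(seq_along(gms), function(i) c(lo[i], hi[i])),
                  names(gms))
}
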