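#' Synthetic MESF standard kit definition
#'
#' A SYNTHETIC stand-in for a five-population PE calibration kit: a
#' certified blank plus four levels. The geometric-mean levels echo the
#' magnitudes a FACSCalibur-class instrument reports for such a kit (top
#' two populations around 278 and 1443); the assigned MESF values are
#' synthetic (100 x GM, i.e. an exact slope-1/intercept-2 log10-log10
#' line) because real kits carry lot-specific certificates that must be
#' supplied by the user.
#'
#' @return Data frame with columns `label`, `mesf`, `gm`.
#' @export
default_standards <- function() {
  data.frame(
    label = c("blank", "bead1", "bead2", "bead3", "bead4"),
    mesf = c(0, 3000, 6500, 27800, 144300),
    gm = c(2, 30, 65, 278, 1443),
    stringsAsFactors = FALSE
  )
}

#' Default simulated conjugate panel
#'
#' Six PE conjugates with initial brightness (FI, geometric mean) and
#' 18-month total fluorescence decrease spanning the regimes seen in
#' long-term reagent stability studies: a bright stable conjugate that
#' exceeds the calibration range (`B2`), mid-brightness conjugates with
#' mild (`A1`) to severe (`A2`, `A3`) decay, and two more (`C`, `D`) in
#' between.
#'
#' @return Data frame with columns `id`, `gm0` (initial FI),
#'   `total_decrease` (fraction lost over 18 months).
#' @export
default_conjugates <- function() {
  data.frame(
    id = c("A1", "A2", "A3", "B2", "C", "D"),
    gm0 = c(1633.3, 1250.6, 932.5, 4564, 1770, 2569),
    total_decrease = c(0.30, 0.79, 0.77, 0.30, 0.60, 0.48),
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration
#'
#' Parameterizes the generative model behind every synthetic acquisition:
#' lognormal single-bead fluorescence, normal scatter with exact 2x
#' doublets, geometric per-month decay per conjugate, and a multiplicative
#' instrument-sensitivity drift applied to everything acquired inside the
#' drift window.
#'
#' @param n_events Events per simulated tube; default 2000 (the minimum
#'   gated-event rule of the acquisition protocol).
#' @param sigma_log Lognormal shape of conjugate FL2 populations; default
#'   0.35.
#' @param conjugates Data frame as [default_conjugates()].
#' @param standards Data frame as [default_standards()].
#' @param standards_sigma Lognormal shape of standard-bead populations
#'   (tight, uniform beads); default 0.10.
#' @param horizon_months Span over which `total_decrease` applies; default
#'   18.
#' @param drift_window `c(first, last)` months of the instrument-drift
#'   episode; default `c(4, 7)`.
#' @param drift_factor Multiplicative sensitivity factor inside the window;
#'   default 0.8 (a 20% dip).
#' @param doublet_frac Fraction of events that are 2x aggregates; default
#'   0.03.
#' @param scatter Named list: `fsc_mean`, `fsc_sd`, `ssc_mean`, `ssc_sd`.
#' @param code_fl4 Default FL4 geometric mean of the (single) bead code.
#' @param fl4_sigma Lognormal shape of the FL4 code signal; default 0.2.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_events = 2000L, sigma_log = 0.35,
                       conjugates = default_conjugates(),
                       standards = default_standards(),
                       standards_sigma = 0.10, horizon_months = 18,
                       drift_window = c(4, 7), drift_factor = 0.8,
                       doublet_frac = 0.03,
                       scatter = list(fsc_mean = 500, fsc_sd = 50,
                                      ssc_mean = 300, ssc_sd = 40),
                       code_fl4 = 500, fl4_sigma = 0.2) {
  stopifnot(n_events >= 1, sigma_log > 0, standards_sigma > 0,
            drift_factor > 0, doublet_frac >= 0, doublet_frac < 1,
            all(conjugates$gm0 > 0),
            all(conjugates$total_decrease >= 0),
            all(conjugates$total_decrease < 1))
  conjugates$monthly_decay <-
    1 - (1 - conjugates$total_decrease)^(1 / horizon_months)
  structure(
    list(n_events = as.integer(n_events), sigma_log = sigma_log,
         conjugates = conjugates, standards = standards,
         standards_sigma = standards_sigma,
         horizon_months = horizon_months,
         drift_window = drift_window, drift_factor = drift_factor,
         doublet_frac = doublet_frac, scatter = scatter,
         code_fl4 = code_fl4, fl4_sigma = fl4_sigma),
    class = "sim_config"
  )
}

#' Simulate one bead acquisition
#'
#' Single-bead fluorescence is lognormal: `FL2 ~ lognormal(ln gm,
#' sigma_log)` so the population's true geometric mean is exactly `gm`; FL4
#' is lognormal around the bead-code GM, FL1 around `fl1_gm` (background
#' autofluorescence unless a FITC stain is being simulated). Scatter is
#' normal, truncated at zero. A `doublet_frac` of events are exact 2x
#' aggregates in every channel.
#'
#' @param n Number of events.
#' @param gm Target FL2 geometric mean (> 0).
#' @param sigma_log Lognormal shape of FL2.
#' @param code_fl4 FL4 geometric mean of the bead code.
#' @param fl4_sigma Lognormal shape of FL4.
#' @param fl1_gm FL1 geometric mean (default 2: autofluorescence).
#' @param fl1_sigma Lognormal shape of FL1.
#' @param scatter Named list (`fsc_mean`, `fsc_sd`, `ssc_mean`, `ssc_sd`).
#' @param doublet_frac Fraction of 2x doublets in `[0, 1)`.
#' @param seed Optional integer seed; fixed seed gives identical tables.
#' @param meta Metadata list attached to the table.
#' @return An [event_table()].
#' @export
simulate_population <- function(n, gm, sigma_log = 0.35, code_fl4 = 500,
                                fl4_sigma = 0.2, fl1_gm = 2,
                                fl1_sigma = 0.3,
                                scatter = list(fsc_mean = 500, fsc_sd = 50,
                                               ssc_mean = 300, ssc_sd = 40),
                                doublet_frac = 0.03, seed = NULL,
                                meta = list()) {
  stopifnot(n >= 1, gm > 0, sigma_log > 0, code_fl4 > 0,
            doublet_frac >= 0, doublet_frac < 1)
  if (!is.null(seed)) set.seed(seed)
  fl2 <- stats::rlnorm(n, log(gm), sigma_log)
  fl4 <- stats::rlnorm(n, log(code_fl4), fl4_sigma)
  fl1 <- stats::rlnorm(n, log(fl1_gm), fl1_sigma)
  fsc <- pmax(stats::rnorm(n, scatter$fsc_mean, scatter$fsc_sd), 0)
  ssc <- pmax(stats::rnorm(n, scatter$ssc_mean, scatter$ssc_sd), 0)
  n_dbl <- floor(n * doublet_frac)
  if (n_dbl > 0) {
    idx <- seq_len(n_dbl)  # first events become doublets (order carries no meaning)
    fsc[idx] <- 2 * fsc[idx]
    ssc[idx] <- 2 * ssc[idx]
    fl2[idx] <- 2 * fl2[idx]
    fl4[idx] <- 2 * fl4[idx]
    fl1[idx] <- 2 * fl1[idx]
  }
  ev <- cbind(FSC = fsc, SSC = ssc, FL1 = fl1, FL2 = fl2, FL4 = fl4)
  tab <- event_table(ev, meta = meta)
  attr(tab, "is_doublet") <- seq_len(n) <= n_dbl
  tab
}

#' Simulate the mixed standards tube
#'
#' All five kit populations acquired in one tube, mirroring the
#' one-drop-of-each protocol. The true per-population labels are retained
#' as an attribute so tests can score population recovery without
#' clustering.
#'
#' @param standards Data frame (`label`, `mesf`, `gm`) as
#'   [default_standards()]; >= 2 non-blank populations required.
#' @param n_per_pop Events per population.
#' @param sigma_log Lognormal shape of each standard population.
#' @param blank_label Label of the certified blank.
#' @param seed Optional integer seed.
#' @param ... Passed to [simulate_population()] (scatter, doublet_frac...).
#' @return An [event_table()] with attribute `"population"` (per-event true
#'   label) and the standards definition in `meta$standards`.
#' @export
simulate_standard_tube <- function(standards, n_per_pop = 2000L,
                                   sigma_log = 0.10,
                                   blank_label = "blank", seed = NULL,
                                   ...) {
  if (sum(standards$label != blank_label) < 2L) {
    stop("need >= 2 non-blank standard populations")
  }
  if (!is.null(seed)) set.seed(seed)
  tabs <- lapply(seq_len(nrow(standards)), function(i) {
    simulate_population(n_per_pop, gm = standards$gm[i],
                        sigma_log = sigma_log, ...)
  })
  ev <- do.call(rbind, lapply(tabs, function(t) t$events))
  tab <- event_table(ev, meta = list(
    sample_id = "standards_tube",
    standards = standards, blank_label = blank_label))
  attr(tab, "population") <- rep(standards$label, each = n_per_pop)
  tab
}

#' Measure an MESF standard set from a simulated standards tube
#'
#' Uses the tube's retained population labels to compute each population's
#' FL2 geometric mean and pair it with its assigned MESF.
#'
#' @param tube Output of [simulate_standard_tube()].
#' @return An [mesf_standard_set()].
#' @export
measure_standard_tube <- function(tube) {
  labels <- attr(tube, "population")
  standards <- tube$meta$standards
  if (is.null(labels) || is.null(standards)) {
    stop("tube does not carry population labels / standards definition")
  }
  gm <- vapply(standards$label, function(l) {
    geometric_mean(channel_values(tube, "FL2")[labels == l])
  }, numeric(1))
  mesf_standard_set(standards$label, standards$mesf, unname(gm),
                    blank_label = tube$meta$blank_label)
}

drift_multiplier <- function(month, config) {
  w <- config$drift_window
  if (!is.null(w) && length(w) == 2L && month >= w[1] && month <= w[2]) {
    config$drift_factor
  } else {
    1
  }
}

#' Simulate an 18-month-style stability study
#'
#' For each month, one tube per conjugate plus the concurrent standards
#' tube. The conjugate's true geometric mean at month `t` is
#' `gm0 * (1 - decay)^t * drift(t)`; standards are `gm * drift(t)`; the
#' drift multiplier equals `drift_factor` inside the drift window and 1
#' elsewhere, so the instrument episode hits conjugates and standards
#' simultaneously. Ground truth sufficient to score every downstream
#' verdict is returned alongside the acquisitions.
#'
#' @param config A [sim_config()].
#' @param months Ordered vector of acquisition months; default `0:18`.
#' @param seed Integer seed; the whole study is reproducible from it.
#' @return A `stability_study`: list with `months`, `acquisitions` (per
#'   month: named conjugate [event_table()]s and the standards tube) and
#'   `truth` (true GMs per conjugate/month, drift-window months, true decay
#'   ordering).
#' @export
simulate_stability_study <- function(config = sim_config(), months = 0:18,
                                     seed = NULL) {
  stopifnot(!is.unsorted(months))
  if (!is.null(seed)) set.seed(seed)
  cj <- config$conjugates
  truth_gm <- matrix(NA_real_, nrow = nrow(cj), ncol = length(months),
                     dimnames = list(cj$id, paste0("m", months)))
  acquisitions <- vector("list", length(months))
  names(acquisitions) <- paste0("m", months)
  for (j in seq_along(months)) {
    t <- months[j]
    drift <- drift_multiplier(t, config)
    tubes <- vector("list", nrow(cj))
    names(tubes) <- cj$id
    for (i in seq_len(nrow(cj))) {
      gm_t <- cj$gm0[i] * (1 - cj$monthly_decay[i])^t * drift
      truth_gm[i, j] <- gm_t
      tubes[[i]] <- simulate_population(
        config$n_events, gm = gm_t, sigma_log = config$sigma_log,
        code_fl4 = config$code_fl4, fl4_sigma = config$fl4_sigma,
        scatter = config$scatter, doublet_frac = config$doublet_frac,
        meta = list(sample_id = sprintf("%s_m%d", cj$id[i], t),
                    conjugate = cj$id[i], timepoint = t))
    }
    std <- config$standards
    std$gm <- std$gm * drift
    standard_tube <- simulate_standard_tube(
      std, n_per_pop = config$n_events, sigma_log = config$standards_sigma,
      scatter = config$scatter, doublet_frac = config$doublet_frac,
      code_fl4 = config$code_fl4)
    # restore nominal assigned values: drift affects measurement, not the
    # kit's certificate
    standard_tube$meta$standards$gm <- config$standards$gm
    acquisitions[[j]] <- list(month = t, conjugates = tubes,
                              standard_tube = standard_tube)
  }
  drift_months <- months[vapply(months, function(t) {
    drift_multiplier(t, config) != 1
  }, logical(1))]
  structure(
    list(months = months,
         acquisitions = acquisitions,
         truth = list(
           gm = truth_gm,
           drift_months = drift_months,
           decay_order = cj$id[order(cj$monthly_decay)],
           conjugates = cj)),
    class = "stability_study"
  )
}

#' Simulate the secondary-stain (FITC) discrimination experiment
#'
#' Two paired acquisitions of the same conjugate-coupled beads carrying a
#' FITC secondary stain against the antibody: one kept protected (2-8 C,
#' dark) and one exposed (room temperature + light, two weeks). Exposure
#' multiplies the PE geometric mean by `fade` and the FITC geometric mean
#' by `fitc_retention`, independently.
#'
#' @param pe_gm Protected PE (FL2) geometric mean.
#' @param fitc_gm Protected FITC (FL1) geometric mean.
#' @param fade PE retained fraction under exposure (> 0).
#' @param fitc_retention FITC retained fraction under exposure (> 0).
#' @param n Events per tube.
#' @param sigma_log Lognormal shape for both channels.
#' @param seed Optional integer seed.
#' @param ... Passed to [simulate_population()].
#' @return List with `protected` and `exposed` [event_table()]s and
#'   `truth` (the factors used).
#' @export
simulate_secondary_stain <- function(pe_gm = 731, fitc_gm = 80,
                                     fade = 0.077, fitc_retention = 0.89,
                                     n = 5000L, sigma_log = 0.25,
                                     seed = NULL, ...) {
  stopifnot(pe_gm > 0, fitc_gm > 0, fade > 0, fitc_retention > 0)
  if (!is.null(seed)) set.seed(seed)
  protected <- simulate_population(
    n, gm = pe_gm, sigma_log = sigma_log, fl1_gm = fitc_gm,
    fl1_sigma = sigma_log,
    meta = list(sample_id = "protected", condition = "2-8C dark"), ...)
  exposed <- simulate_population(
    n, gm = pe_gm * fade, sigma_log = sigma_log,
    fl1_gm = fitc_gm * fitc_retention, fl1_sigma = sigma_log,
    meta = list(sample_id = "exposed", condition = "RT light"), ...)
  list(protected = protected, exposed = exposed,
       truth = list(fade = fade, fitc_retention = fitc_retention))
}

#' Simulate a concentration-optimization panel
#'
#' Emulates the coupling-concentration experiment: brightness saturates
#' with concentration (`gm(c) = gm_max * c / (c + K)`) while the lognormal
#' shape — hence the CV — shrinks as coupling gets more homogeneous
#' (`sigma` interpolated in log-concentration between `sigma_range[1]` at
#' the lowest level and `sigma_range[2]` at the highest). Each replicate is
#' a full simulated acquisition pushed through the scatter gate and
#' [population_stats()].
#'
#' @param levels Concentrations (ug/mL); default `c(0.5, 1, 2.5, 5)`.
#' @param n_reps Replicate acquisitions per level; default 3.
#' @param n_events Events per acquisition; default 2000.
#' @param gm_max Saturating brightness; default 2000.
#' @param K Half-saturation concentration; default 1.
#' @param sigma_range `c(sigma at lowest, sigma at highest)`; default
#'   `c(0.45, 0.18)`.
#' @param seed Optional integer seed.
#' @return Data frame with columns `level`, `replicate`, `geo_mean`,
#'   `cv_percent` (one row per replicate), suitable for
#'   [optimize_concentration()]. True per-level parameters are attached as
#'   attribute `"truth"`.
#' @export
simulate_concentration_panel <- function(levels = c(0.5, 1, 2.5, 5),
                                         n_reps = 3L, n_events = 2000L,
                                         gm_max = 2000, K = 1,
                                         sigma_range = c(0.45, 0.18),
                                         seed = NULL) {
  stopifnot(length(levels) >= 2L, n_reps >= 2L)
  if (!is.null(seed)) set.seed(seed)
  levels <- sort(levels)
  lfrac <- (log(levels) - log(min(levels))) /
           (log(max(levels)) - log(min(levels)))
  sigma <- sigma_range[1] + (sigma_range[2] - sigma_range[1]) * lfrac
  gm <- gm_max * levels / (levels + K)
  rows <- list()
  for (i in seq_along(levels)) {
    for (r in seq_len(n_reps)) {
      tab <- simulate_population(n_events, gm = gm[i], sigma_log = sigma[i])
      gate <- gate_singlets(tab)
      st <- population_stats(tab, gate, channel = "FL2")
      rows[[length(rows) + 1L]] <- data.frame(
        level = levels[i], replicate = r, geo_mean = st$geo_mean,
        cv_percent = st$cv_percent)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "truth") <- data.frame(level = levels, gm = gm, sigma = sigma)
  out
}
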