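test_that("simulation is deterministic for a fixed seed", {
  a <- simulate_population(1000, gm = 500, seed = 601)
  b <- simulate_population(1000, gm = 500, seed = 601)
  expect_identical(a$events, b$events)
  c_ <- simulate_population(1000, gm = 500, seed = 602)
  expect_false(identical(a$events, c_$events))

  s1 <- simulate_stability_study(sim_config(n_events = 100), 0:3, seed = 603)
  s2 <- simulate_stability_study(sim_config(n_events = 100), 0:3, seed = 603)
  expect_identical(s1$acquisitions$m2$standard_tube$events,
                   s2$acquisitions$m2$standard_tube$events)
})

test_that("simulated populations recover their configured moments", {
  tab <- simulate_population(1e5, gm = 500, sigma_log = 0.4,
                             doublet_frac = 0, seed = 604)
  fl2 <- channel_values(tab, "FL2")
  expect_equal(geometric_mean(fl2), 500, tolerance = 0.01)
  expect_equal(cv_percent(fl2), lognormal_cv(0.4), tolerance = 0.02)
  # FL4 code signal too
  expect_equal(geometric_mean(channel_values(tab, "FL4")), 500,
               tolerance = 0.02)
})

test_that("without doublets no events sit beyond a wide scatter gate", {
  tab <- simulate_population(20000, gm = 500, doublet_frac = 0, seed = 605)
  gate <- gate_singlets(tab, k = 6)
  # normal tail beyond 6 * 1.4826 MAD is negligible at n = 2e4
  expect_gte(gate$n_kept, 19995)
})

test_that("the mixed standards tube recovers per-population GMs", {
  set.seed(606)
  tube <- simulate_standard_tube(default_standards(), n_per_pop = 2000,
                                 doublet_frac = 0)
  std <- measure_standard_tube(tube)
  expect_equal(std$populations$geo_mean, default_standards()$gm,
               tolerance = 0.02)
  # two seeds: different events, same population GMs within tolerance
  tube2 <- simulate_standard_tube(default_standards(), n_per_pop = 2000,
                                  doublet_frac = 0, seed = 607)
  expect_false(identical(tube$events, tube2$events))
  expect_equal(measure_standard_tube(tube2)$populations$geo_mean,
               std$populations$geo_mean, tolerance = 0.05)
})

test_that("a blank-only kit cannot be simulated or calibrated", {
  blankish <- data.frame(label = c("blank", "b1"), mesf = c(0, 1e3),
                         gm = c(2, 30))
  expect_error(
    simulate_standard_tube(blankish[1, , drop = FALSE], n_per_pop = 10),
    "non-blank")
  expect_error(fit_calibration(mesf_standard_set(
    blankish$label, blankish$mesf, blankish$gm)), "calibration error")
})

test_that("generative decay maps to the downstream percent decrease", {
  decay_total <- 0.30  # the mild-decay regime: (1 - d)^18 = 0.70
  cfg <- sim_config(
    n_events = 2000,
    conjugates = data.frame(id = "K", gm0 = 1600,
                            total_decrease = decay_total),
    drift_window = NULL)
  study <- simulate_stability_study(cfg, months = c(0, 6, 12, 18),
                                    seed = 608)
  res <- analyze_stability_study(study)
  expect_equal(res$series$K$pct_decrease, 30, tolerance = 0.1)
  expect_length(res$drift_report$flagged, 0)

  # no decay, no drift: flat series, delta-FI ~ 0 relative to FI scale
  cfg0 <- sim_config(n_events = 2000,
                     conjugates = data.frame(id = "K", gm0 = 1600,
                                             total_decrease = 0),
                     drift_window = NULL)
  res0 <- analyze_stability_study(
    simulate_stability_study(cfg0, months = c(0, 9, 18), seed = 609))
  expect_lt(abs(res0$series$K$pct_decrease), 5)
})

test_that("a simulated instrument dip is attributed to exactly its window", {
  cfg <- sim_config(n_events = 1500,
                    conjugates = data.frame(id = "K", gm0 = 1600,
                                            total_decrease = 0.4),
                    drift_window = c(4, 7), drift_factor = 0.8)
  study <- simulate_stability_study(cfg, months = 0:10, seed = 610)
  res <- analyze_stability_study(study)
  expect_equal(res$drift_report$flagged, 4:7)
  att <- res$attributions$K$details$per_timepoint
  expect_true(all(att$attribution[att$timepoint %in% 4:7] == "instrument"))
  expect_false(any(att$attribution[!att$timepoint %in% 4:7] == "instrument"))
})

test_that("secondary-stain simulation reproduces its fade/retention factors", {
  pair <- simulate_secondary_stain(pe_gm = 731, fitc_gm = 80, fade = 0.077,
                                   fitc_retention = 0.89, seed = 611)
  pe_prot <- geometric_mean(channel_values(pair$protected, "FL2"))
  pe_exp <- geometric_mean(channel_values(pair$exposed, "FL2"))
  fitc_prot <- geometric_mean(channel_values(pair$protected, "FL1"))
  fitc_exp <- geometric_mean(channel_values(pair$exposed, "FL1"))
  expect_equal(pe_exp / pe_prot, 0.077, tolerance = 0.02)
  expect_equal(fitc_exp / fitc_prot, 0.89, tolerance = 0.02)
  v <- stain_integrity_check(c(pe_prot, pe_exp), c(fitc_prot, fitc_exp))
  expect_equal(v$verdict, "fluorochrome fading")

  stable <- simulate_secondary_stain(fade = 1, fitc_retention = 1,
                                     seed = 612)
  v2 <- stain_integrity_check(
    c(geometric_mean(channel_values(stable$protected, "FL2")),
      geometric_mean(channel_values(stable$exposed, "FL2"))),
    c(geometric_mean(channel_values(stable$protected, "FL1")),
      geometric_mean(channel_values(stable$exposed, "FL1"))))
  expect_equal(v2$verdict, "stable")

  lost <- simulate_secondary_stain(fade = 0.1, fitc_retention = 0.1,
                                   seed = 613)
  v3 <- stain_integrity_check(
    c(geometric_mean(channel_values(lost$protected, "FL2")),
      geometric_mean(channel_values(lost$exposed, "FL2"))),
    c(geometric_mean(channel_values(lost$protected, "FL1")),
      geometric_mean(channel_values(lost$exposed, "FL1"))))
  expect_equal(v3$verdict, "uncoupling/degradation")
})

test_that("study ground truth is sufficient to score downstream verdicts", {
  cfg <- sim_config(n_events = 200)
  study <- simulate_stability_study(cfg, months = 0:8, seed = 614)
  expect_equal(study$truth$drift_months, 4:7)
  expect_equal(dim(study$truth$gm),
               c(nrow(cfg$conjugates), 9))
  expect_setequal(study$truth$decay_order, cfg$conjugates$id)
})
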