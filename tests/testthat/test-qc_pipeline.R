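test_that("stability series identities hold exactly", {
  s <- build_stability_series("A1", timepoints = c(0, 18),
                              fi = c(1633.3, 1143.3))
  expect_equal(s$delta_fi, 490)
  expect_equal(round(s$pct_decrease, 1), 30.0)
  expect_identical(s$delta_fi, s$fi[[1]] - s$fi[[length(s$fi)]])
  expect_identical(s$pct_decrease, 100 * s$delta_fi / s$fi[[1]])

  flat <- build_stability_series("X", 0:5, rep(100, 6))
  expect_equal(flat$delta_fi, 0)
  expect_equal(flat$pct_decrease, 0)

  # property: identities on random series
  set.seed(501)
  for (i in 1:10) {
    fi <- rlnorm(7, log(1000), 0.5)
    s <- build_stability_series("r", 0:6, fi)
    expect_identical(s$delta_fi, fi[1] - fi[7])
    expect_identical(s$pct_decrease, 100 * s$delta_fi / fi[1])
    expect_true(all(s$excluded_timepoints %in% s$timepoints))
  }
})

test_that("drift-flagged months are excluded from the delta-FI span", {
  drift <- structure(list(flagged = 4:7, timepoints = 0:8),
                     class = "drift_report")
  fi <- c(1000, 990, 980, 970, 700, 690, 680, 950, 940)
  s <- build_stability_series("A", 0:8, fi, drift_report = drift)
  expect_equal(s$excluded_timepoints, 4:7)
  expect_equal(s$first_timepoint, 0)
  expect_equal(s$last_timepoint, 8)
  expect_equal(s$delta_fi, 1000 - 940)
  # with the dip at the end, exclusion changes the endpoint
  fi2 <- c(1000, 990, 980, 970, 960, 950, 700, 690, 680)
  drift2 <- structure(list(flagged = 6:8, timepoints = 0:8),
                      class = "drift_report")
  s2 <- build_stability_series("A", 0:8, fi2, drift_report = drift2)
  expect_equal(s2$last_timepoint, 5)
  expect_equal(s2$delta_fi, 1000 - 950)
  # opt-out: raw full span
  s3 <- build_stability_series("A", 0:8, fi2, drift_report = drift2,
                               config = qc_config(use_full_span = TRUE))
  expect_equal(s3$delta_fi, 1000 - 680)
  expect_error(
    build_stability_series("A", 0:2, c(3, 2, 1),
                           drift_report = structure(
                             list(flagged = 1:2, timepoints = 0:2),
                             class = "drift_report")),
    "series error")
})

test_that("stability ranking orders by ascending delta-FI, brightness separately", {
  mk <- function(id, fi0, fi1, fi_only = FALSE) {
    s <- build_stability_series(id, c(0, 18), c(fi0, fi1))
    s$fi_only <- fi_only
    s
  }
  v <- rank_stability(list(mk("A1", 1633.3, 1143.3),
                           mk("A2", 1250.6, 262.6),
                           mk("A3", 932.5, 214.5)))
  df <- v$details$ranking
  expect_equal(df$conjugate_id, c("A1", "A3", "A2"))
  expect_match(v$verdict, "most stable: A1")
  # brightness ranking is distinct from stability ranking
  expect_equal(df$conjugate_id[df$brightness_rank == 1], "A1")

  tie <- rank_stability(list(mk("X", 100, 50), mk("Y", 200, 150)))
  expect_true(all(tie$details$ranking$stability_rank == 1))
  expect_match(tie$verdict, "tie")

  # an above-range conjugate is ranked on FI with an fi_only tag
  v2 <- rank_stability(list(mk("A1", 1633.3, 1143.3),
                            mk("B2", 4564, 4000, fi_only = TRUE)))
  expect_true(v2$details$ranking$fi_only[
    v2$details$ranking$conjugate_id == "B2"])
})

test_that("mismatched spans warn but still rank", {
  s1 <- build_stability_series("A", c(0, 18), c(100, 60))
  s2 <- build_stability_series("B", c(4, 18), c(100, 80))
  v <- rank_stability(list(s1, s2))
  expect_match(v$details$comparability_warning, "spans differ")
  expect_equal(v$details$ranking$conjugate_id[1], "B")
})

test_that("decline attribution separates instrument drift from true decay", {
  drift_none <- structure(list(flagged = numeric(0), timepoints = 0:6),
                          class = "drift_report")
  declining <- build_stability_series("A", 0:6,
                                      1000 * (1 - 0.1)^(0:6))
  v <- attribute_decline(declining, drift_none)
  expect_equal(v$verdict, "true conjugate decrease")
  expect_equal(v$evidence$n_instrument_timepoints, 0)
  expect_gt(v$evidence$n_conjugate_timepoints, 0)

  # a shared dip-and-recover episode: window is instrument, no true decrease
  drift_win <- structure(list(flagged = 2:4, timepoints = 0:6),
                         class = "drift_report")
  fi <- c(1000, 1000, 800, 800, 800, 1000, 1000)
  dipper <- build_stability_series("B", 0:6, fi, drift_report = drift_win)
  v2 <- attribute_decline(dipper, drift_win)
  lab <- v2$details$per_timepoint$attribution
  expect_true(all(lab[3:5] == "instrument"))
  expect_equal(v2$verdict, "no true decrease")

  # composite: decline AND a mid-series instrument dip; endpoints decide
  fi3 <- c(1000, 950, 700, 680, 660, 850, 800)
  dip_mid <- build_stability_series("C", 0:6, fi3, drift_report = drift_win)
  v3 <- attribute_decline(dip_mid, drift_win)
  lab3 <- v3$details$per_timepoint$attribution
  expect_true(all(lab3[3:5] == "instrument"))
  expect_equal(v3$verdict, "true conjugate decrease")

  # invariant: "instrument" only where the standards flag is set
  flagged_set <- v3$details$per_timepoint$timepoint[lab3 == "instrument"]
  expect_true(all(flagged_set %in% drift_win$flagged))
  expect_error(attribute_decline(declining, structure(
    list(flagged = numeric(0), timepoints = 20:25),
    class = "drift_report")), "attribution error")
})

test_that("stain integrity verdicts separate fading from uncoupling", {
  a1 <- stain_integrity_check(pe = c(731, 56), fitc = c(80, 71),
                              subject = "A1")
  expect_equal(a1$verdict, "fluorochrome fading")
  expect_equal(a1$evidence$pe_retention, 56 / 731)
  expect_equal(a1$evidence$fitc_retention, 71 / 80)

  a2 <- stain_integrity_check(pe = c(580, 45), fitc = c(185, 166))
  expect_equal(a2$verdict, "fluorochrome fading")

  both_lost <- stain_integrity_check(pe = c(400, 40), fitc = c(100, 10))
  expect_equal(both_lost$verdict, "uncoupling/degradation")

  stable <- stain_integrity_check(pe = c(700, 690), fitc = c(100, 95))
  expect_equal(stable$verdict, "stable")

  odd <- stain_integrity_check(pe = c(700, 690), fitc = c(100, 10))
  expect_equal(odd$verdict, "indeterminate")
  expect_error(stain_integrity_check(pe = c(-1, 5), fitc = c(1, 1)))
})

test_that("CV comparison uses a two-sided Welch test on replicate CVs", {
  v <- compare_cv(cv_low = c(30, 31, 32), cv_high = c(10, 11, 12))
  expect_equal(v$verdict, "more homogeneous at high concentration")
  expect_lte(v$p_values$t_test, 0.05)
  # oracle: Welch t for these groups
  oracle <- t.test(c(10, 11, 12), c(30, 31, 32))
  expect_equal(v$evidence$t_statistic, unname(oracle$statistic))

  same <- compare_cv(c(20, 21), c(20, 21))
  expect_equal(same$verdict, "no significant homogeneity difference")

  close <- compare_cv(cv_low = c(25, 26, 27), cv_high = c(24, 25, 26))
  expect_equal(close$evidence$mean_cv_high - close$evidence$mean_cv_low, -1)
  expect_equal(close$p_values$t_test,
               t.test(c(24, 25, 26), c(25, 26, 27))$p.value)

  degen <- compare_cv(c(20, 20), c(20, 20))
  expect_equal(degen$verdict, "indistinguishable")
})

test_that("compare_groups matches oracle t and ANOVA computations", {
  same <- compare_groups(list(c(1, 2, 3), c(1, 2, 3)), "t_test")
  expect_equal(same$p_value, 1)

  tt <- compare_groups(list(c(1, 2, 3), c(11, 12, 13)), "t_test")
  expect_equal(tt$statistic, -12.24745, tolerance = 1e-6)
  expect_lt(tt$p_value, 0.001)
  expect_true(tt$significant)

  set.seed(502)
  g <- list(rnorm(8), rnorm(8, 1), rnorm(8, 2))
  an <- compare_groups(g, "anova")
  df <- data.frame(value = unlist(g),
                   grp = factor(rep(1:3, each = 8)))
  oracle <- summary(aov(value ~ grp, df))[[1]]
  expect_equal(an$statistic, oracle$`F value`[1])
  expect_equal(an$p_value, oracle$`Pr(>F)`[1])

  degen <- compare_groups(list(c(5, 5), c(5, 5)), "t_test")
  expect_true(degen$undefined)
  expect_error(compare_groups(list(1:3, 4:6, 7:9), "t_test"),
               "exactly 2 groups")
})

test_that("concentration optimization picks max-FI/min-CV and flags conflicts", {
  panel <- simulate_concentration_panel(seed = 503)
  v <- optimize_concentration(panel)
  expect_equal(v$evidence$choice, 5)
  expect_lte(v$p_values$anova, 0.05)
  expect_match(v$verdict, "optimal level: 5")

  # null panel: no level preferred, defaults to the lowest concentration
  set.seed(504)
  null_panel <- data.frame(
    level = rep(c(0.5, 1, 2.5, 5), each = 3),
    replicate = rep(1:3, 4),
    geo_mean = rnorm(12, 1000, 50),
    cv_percent = rnorm(12, 30, 2))
  vn <- optimize_concentration(null_panel)
  expect_gt(vn$p_values$anova, 0.05)
  expect_equal(vn$verdict, "no level preferred")
  expect_equal(vn$evidence$choice, 0.5)

  # FI and CV both increasing: conflict is flagged, nothing chosen silently
  conflict <- data.frame(
    level = rep(c(0.5, 5), each = 3), replicate = rep(1:3, 2),
    geo_mean = c(500, 510, 490, 2000, 2010, 1990),
    cv_percent = c(20, 21, 19, 40, 41, 39))
  vc <- optimize_concentration(conflict)
  expect_match(vc$verdict, "conflict")
  expect_true(is.na(vc$evidence$choice))

  expect_error(optimize_concentration(
    data.frame(level = c(5, 5), geo_mean = c(1, 2), cv_percent = c(1, 2))),
    "configuration error")
})

test_that("qc_verdict validates evidence and p-values", {
  expect_error(qc_verdict("s", "homogeneity", "ok", evidence = list()),
               "evidence")
  expect_error(qc_verdict("s", "homogeneity", "ok", evidence = list(x = 1),
                          p_values = list(p = 0)), "p-values")
  expect_error(qc_config(alpha = 1.2))
})
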