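---
title: "Methods: bead-based QC of fluorescent antibody conjugates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bead-based QC of fluorescent antibody conjugates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conjuqc)
```

## The problem

Antibody–fluorochrome conjugates (anti-IgG–PE, anti-HBsAg–PE and the like)
are the reporter reagents of bead-based multiplex immunoassays. The
traditional release test — the spectrophotometric fluorochrome-to-protein
ratio — does not measure fluorescence emission under laser excitation, so a
conjugate can pass it and still perform poorly on the instrument.
`conjuqc` implements a flow-cytometric alternative: the conjugate is coupled
to carboxylated microspheres, acquired on a FACSCalibur-class cytometer, and
judged on three histogram statistics plus a quantitative calibration,
repeatedly over months, so that brightness, coupling homogeneity and
long-term stability are all measured on the physics that matters — photons
per bead.

## Data model

Events live in an `event_table`: a matrix of per-event intensities over the
channels FSC, SSC (scatter), FL1 (FITC, the secondary stain), FL2 (PE, the
reporter) and FL4 (the bead-code dye), plus acquisition metadata and a
per-channel amplifier descriptor.

The canonical scale is **linear relative fluorescence**. Log-amplified FCS
parameters (`$PnE = "d,r"` with `d > 0`) are decoded once at read time with
the standard amplifier transform `10^(d * x / PnR)`; linear parameters
(`$PnE = "0,0"`) pass through. Geometric means and the MESF regression are
defined on linear intensities, so decoding early keeps every downstream
formula simple. Vendor analysis software does not document whether its
statistics run on channel or linear values; computing on linear values is
this package's declared choice, and the CSV dialect (header
`FSC,SSC,FL1,FL2,FL4`) exists so that fixtures and tests never need binary
files.

## Gating

The acquisition protocol draws a manual gate around the singlet bead cloud
on the FSC × SSC dot plot and requires at least 2000 events inside it. A
manual gate is not reproducible, so `gate_singlets()` formalizes it as an
axis-aligned box centred on the per-axis median with half-widths `k · MAD`
(default `k = 4`), **iterated to a fixed point**: the box is re-estimated on
the kept events until the kept set stops changing. Iteration buys
idempotence — gating the gated subset returns the whole subset — which a
single pass cannot guarantee. Doublets, modelled as exact 2× aggregates in
every channel, sit at twice the scatter centre and fall far outside the box.
Degenerate axes (zero MAD) receive an epsilon half-width so identical-scatter
data are kept and half-widths stay positive. `check_min_events()` applies
the ≥ 2000-event rule; failures are flagged, never silently dropped.

Bead codes are classified on FL4 with disjoint half-open intervals. When
intervals are derived from reference geometric means
(`derive_code_bounds()`), cut points sit at log-space midpoints because the
code populations are lognormal; ten-fold separated codes at 20% CV then
misclassify a negligible fraction of events.

## The three histogram statistics

For a gated population on one channel, `population_stats()` reports:

* **FI** — the geometric mean `exp(mean(log v))`, the brightness statistic.
  Non-positive values are excluded with a logged count; if more than 1% of
  events are excluded the statistic is flagged, because at that point the
  acquisition, not the formula, is the problem.
* **CV%** — `100 · SD / mean` on linear intensities with the n−1
  denominator; the coupling-homogeneity statistic (narrow peak = homogeneous
  coupling). A robust variant (`100 · 0.7413 · IQR / median`) is available
  but not the default, to stay comparable with vendor software.
* **% positive** — the fraction of events above a linear threshold. The
  default threshold is the 99th percentile of an uncoupled-bead control,
  because the protocol carries such controls but no published threshold
  definition exists.

On lognormal populations FI estimates `e^mu` and CV% estimates
`100·sqrt(exp(sigma^2) − 1)`; the test suite verifies both recoveries at
n = 10^5 within 1% and 2% respectively.

## MESF calibration

Quantitative fluorescence cytometry calibrates the intensity axis in
molecules of equivalent soluble fluorochrome using a five-population
standard kit (certified blank + four PE levels) acquired immediately after
the samples. The vendor's calibration software is a black box, so
`fit_calibration()` adopts the standard QFCM model: ordinary least squares
of `log10(assigned MESF)` on `log10(measured GM)` over the **non-blank**
standards. The blank is excluded from the fit and used only to define the
lower detection limit (the model evaluated at the blank's GM); the brightest
standard's GM is the upper limit. `assign_mesf()` inverts the line and
flags samples: `above_range` values are still reported numerically but are
hard-marked non-evaluable — downstream stability statements for such
conjugates use raw FI only, which is exactly how over-range conjugates must
be handled when re-dilution would change the coupling conditions being
studied.

The calibration is refitted at every timepoint from the concurrent
standards tube; instrument settings are assumed fixed, but the refit makes
each month's MESF values self-consistent.

## Instrument drift versus true decay

`monitor_standards()` tracks each non-blank standard's GM relative to
baseline. A timepoint is flagged **instrument drift** only when *all*
standards move beyond the tolerance (default 10%) *in the same direction*:
independent, chemically stable beads moving together is the signature of a
sensitivity change in the instrument, not of the beads. A lone standard
excursion raises an inconsistent-standard warning instead.

`build_stability_series()` computes the two headline stability numbers,
`ΔFI = FI(first) − FI(last)` and `% decrease = 100 · ΔFI / FI(first)`,
taking first/last from the **non-flagged** timepoints by default. Formal
exclusion of the drift window is this package's reproducible version of
reasoning "around" a transient sensitivity dip; `use_full_span = TRUE`
preserves the raw-span alternative since published ΔFI values may include
the dip months. `attribute_decline()` then labels each below-tolerance
timepoint `instrument` (standards flagged) or `conjugate` (standards flat)
and issues "true conjugate decrease" only when the decline survives on
non-flagged timepoints — a timepoint is never attributed to the instrument
unless the standards flag is set there.

`rank_stability()` orders conjugates by ascending ΔFI and, separately, by
initial FI, because brightness and stability rankings routinely disagree
(the brightest conjugate is often not the most stable one).

## Decision thresholds

* **Concentration choice** (`optimize_concentration()`): the optimum is the
  level with maximal FI *and* minimal CV, ties toward the lower
  concentration; a one-way ANOVA over replicate FIs must be significant at
  `alpha = 0.05`, otherwise no level is preferred and the lowest is the
  default. If FI and CV point at different levels the verdict flags the
  conflict rather than choosing. Dilution series run through the same
  operation with dilutions as ordinal levels.
* **Homogeneity** (`compare_cv()`): two-sided Welch t-test on replicate
  CVs; "more homogeneous at high concentration" requires both the lower
  mean CV and significance. Welch rather than pooled is the default because
  peak-width variance differs across concentrations; `pooled_t = TRUE`
  restores the classic test.
* **Stain integrity** (`stain_integrity_check()`): after a light/room-
  temperature stress, PE retention < 50% with FITC retention ≥ 75% reads
  "fluorochrome fading"; both below their thresholds reads
  "uncoupling/degradation"; both retained, "stable"; PE retained with FITC
  lost, "indeterminate". The 50%/75% defaults were chosen to separate the
  two regimes cleanly — observed fading events sit near 8–10% PE retention
  with ≈ 78–90% FITC retention, far from either threshold — and both are
  configurable.
* No multiple-testing correction is applied by default (each comparison is
  reported at its own `alpha = 0.05`, matching how such QC comparisons are
  customarily read); a Holm option exists.

## The synthetic-data generator

`simulate_population()` draws FL2, FL4 and FL1 as lognormals around their
target geometric means, scatter as truncated normals, and converts a fixed
fraction of events into exact 2× doublets. Lognormal is the single noise
family: it matches the unimodal log-scale peaks such acquisitions show and
keeps closed-form checks (GM = `e^mu`, CV from sigma) available.
`simulate_standard_tube()` mixes the five standard populations into one
tube, retaining true labels for scoring. `simulate_stability_study()`
applies geometric per-month decay per conjugate
(`gm_t = gm0 · (1 − d)^t`) and a multiplicative sensitivity factor (default
0.8 over months 4–7) to *everything* acquired inside the drift window, and
emits ground truth sufficient to score every downstream verdict.
`simulate_secondary_stain()` generates the protected/exposed pair with
independent PE-fade and FITC-retention factors.

Default study conditions: 2000 events per tube (the minimum-event rule),
conjugate lognormal shape 0.35 (CV ≈ 36%, a typical coupled-bead peak),
standards shape 0.10 (uniform hard-dyed beads), six conjugates whose initial
FI and 18-month total decrease span the regimes a long-term study
encounters — including one bright conjugate above the calibration range —
and a synthetic kit whose GM levels (2, 30, 65, 278, 1443) sit where a
FACSCalibur places such a kit. The kit's assigned MESF values are
**synthetic** (100 × GM, an exact slope-1/intercept-2 line): real kits
carry lot-specific certificates that users must supply.

What the generator does *not* emulate: spectral spillover and compensation,
photomultiplier saturation, electronic (additive) noise, carryover between
tubes, day-to-day operator variation in gating, or photobleaching kinetics
beyond a constant monthly rate. Passing tests therefore demonstrate that
the analysis logic is correct under the stated statistical structure, not
that any particular real conjugate is stable.

## Numerical choices and problem sizes

Estimator-recovery tests run at n = 10^5 events; study-level tests use
500–2000 events per tube over 19 monthly timepoints and repeat end-to-end
recoveries across 20 seeds; the type-I-error check uses 1000 null
replications of a 3 × 10 ANOVA. These sizes give sampling errors an order
of magnitude below every tolerance asserted (e.g. GM standard error ≈ 1.6%
per tube at 500 events, against a 20% drift signal and a 10% tolerance).
Ties in rankings use minimum rank; equal-ΔFI sets are reported as ties.
Degenerate statistical inputs (zero variance everywhere) return an explicit
undefined-test flag rather than an error, because a pipeline run over many
acquisitions must keep going.

## Known limitations

* The scatter gate is a robust box, not a cluster model; pathological
  scatter distributions (heavy bridging between singlets and doublets) will
  blur its edge. `k` is configurable.
* MESF values are instrument- and settings-specific; the package never
  attempts cross-instrument harmonization or antibody-binding-capacity
  conversion.
* Replicate geometric means are treated as independent acquisitions in all
  group tests; if replicates are re-analyses of one acquisition the p-values
  are optimistic.
* Drift attribution is binary per timepoint; a slow monotone instrument
  drift that never crosses the tolerance in a coherent way will be read as
  conjugate decay.
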