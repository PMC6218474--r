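---
title: "Methods: cumulative human footprint and extinction-risk transitions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cumulative human footprint and extinction-risk transitions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameter choices and numerical
conventions behind `footprintr`, and states precisely what a green test
establishes — and what it does not.

## 1. The cumulative index

The human-footprint (HFP) index aggregates eight pressure layers, each
standardized to a 0–10 score, into a single per-cell integer in [0, 50].
The categorical rules (built = 10, cropland = 7, pasture = 4, railway
buffer = 8, road buffer = 8, waterway bank = 4, density above 1,000
people km⁻² = 10, lit-cell deciles 1–10) are fixed by the index definition.
Three interior details are *not* fixed by it and are package choices:

* **Population-density log scale.** Below the 1,000 km⁻² cutoff we use
  `s = min(10, 3.333 · log10(D + 1))`. The constant makes the continuous
  branch reach 10 exactly at D ≈ 1,000, so the rule has no discontinuity at
  the cutoff. Any score-preserving reparameterization would do; this one is
  the simplest that honours both stated endpoints.
* **Night-light deciles.** Deciles are computed over the strictly positive
  cells of the *same epoch's* layer (`ceiling(10 · rank_min / n_lit)`), zeros
  score 0, and ties take the lower decile via the minimum rank. Because the
  decile boundaries are epoch-relative, a cell's light score can fall between
  epochs even when its radiance did not — one of the reasons decreases exist
  and the "no change" clamp (section 3) matters.
* **Distance decay.** Roads score 8 inside the 500-m direct buffer; the
  indirect effect starts at 4 (half the direct score) and decays as
  `4·exp(−k(d − 0.5))` with `k = log(4/0.25)/14.5 ≈ 0.191 km⁻¹`, chosen so
  the score at 15 km equals 0.25 — the largest value that still rounds to
  zero in the integer index. Waterways decay from 4 at the bank with the
  analogous construction (`k = log(4/0.25)/15`). Railways have no indirect
  component. The endpoints (direct scores, 15-km horizon, decay-to-zero) are
  given; the interior shape and the 0.25 target are documented package
  choices and live in `decay_params()`, not in code constants.

Built, cropland and pasture are treated as mutually exclusive land-cover
states, which makes the maximum attainable sum exactly
10 + 10 + 10 + 8 + 8 + 4 = 50; the constructor enforces this. The summed
score is rounded **half-up** to an integer (the index is defined on integers
but no rounding rule is stated) and clamped to [0, 50]. Any cell with nodata
in any layer is nodata in the index and excluded from matrices and overlaps.

## 2. Risk-transition classification

Categories are ranked LC(0) < NT(1) < VU(2) < EN(3) < CR(4) < EW(5) < EX(6);
DD and NE carry no rank and are excluded, as are species extinct at the start
of the period. Two classification details were genuinely open:

* **EW at the start.** The exclusion rule names "already extinct" species
  without saying whether extinct-in-the-wild counts. We exclude EW-starters
  by default and expose `exclude_ew_start = FALSE` rather than guess.
* **Totality.** Stated verbatim, the high-risk rule ("threatened or
  near-threatened category retained") leaves retained-EW/EX pairs
  unclassified, which breaks the required exhaustiveness over all 49 ranked
  pairs when EW-starters are kept. We classify *any* retained non-LC category
  as high-risk; this agrees with the stated rule on every pair it defines and
  is total. The enumeration test locks this in.

## 3. Overlaps, thresholds and the clamp

Ranges are rasterized by the **centre-in-polygon** rule (a cell belongs to a
range iff its centre is inside the geometry) — deterministic and checkable
against a brute-force point-in-polygon oracle, which the tests do with an
independent winding-number implementation. Ranges are static across epochs.

Thresholds are **strict** throughout: `extent_above(mask, hfp, t)` is the
range fraction with HFP > t, for t = 0..49. Prose like "HFP ≥ 3" maps to
t = 2; reports carry the strict integer and a convention note, because this
off-by-one is the easiest mistake to make with this analysis. The change in
extent is the difference of range fractions (percentage points of range),
not a ratio. Under the "no change" clamp, each cell's final value is
replaced by `max(initial, final)` before extents are computed, so per-cell
decreases contribute nothing and every delta is nonnegative.

## 4. Sweep statistics

Per threshold, the two groups are summarized by mean delta and a 95%
interval. The shaded-band interval is implemented as **mean ± 1.96·SE**; a
seeded percentile bootstrap (1,000 resamples) is available via
`conf = "bootstrap"`. The band is descriptive, not a multiplicity-corrected
inference; no correction across the 50 thresholds is applied, matching how
such sweeps are usually reported.

Effect size is Cohen's *d* with the pooled SD, oriented positive-group-first
(high-risk minus low-risk). A zero pooled SD or a singleton group yields a
flagged `NA`/`NaN` rather than an error in sweeps. The location test is the
**unpaired rank-sum** (Wilcoxon–Mann–Whitney) form: the source analysis names
a "signed rank" test for what are independent groups, which is internally
inconsistent; we implement the rank-sum and note the discrepancy rather than
invent a pairing. For nA + nB ≤ 12 the p-value is an exact enumeration over
all rank assignments (ties handled naturally); otherwise the normal
approximation with tie correction is used. `effect_profile()` returns the
|d|-maximizing threshold for extent and delta, ties broken toward the lowest
threshold.

## 5. The random-forest model

No random-forest implementation ships with the target environment, so the
package provides one (`src/rf.cpp`): CART trees with Gini splits, bootstrap
resampling, per-node feature subsampling, grown to purity. Defaults are the
conventional 500 trees and ⌊√p⌋ features per split, with 10-fold
**stratified** cross-validation; all of it is seeded (a self-contained
mt19937 stream, so results do not depend on R's global RNG state). Class
imbalance is handled by stratification only — no reweighting — which is why
sensitivity < specificity is the expected pattern on imbalanced draws.

Predictors are the two HFP variables (final-epoch extent above t, and its
clamped delta) plus twelve covariates; range size is deliberately excluded
(circularity with how risk categories are assigned). Categoricals are
integer-encoded with the level maps persisted in the report; treating the
codes as ordered split variables is a simplification a dedicated RF package
would avoid, acceptable here because the synthetic covariates carry no
planted signal. Missing continuous covariates are median-imputed; the
imputation record is kept as an attribute rather than an extra column so the
feature schema stays exactly "14 predictors + label".

Importance is reported two ways: **CV permutation importance** (drop in
held-out accuracy when one predictor is permuted in the test fold, averaged
over folds — chosen over out-of-bag permutation so that importance and
performance come from the same held-out data) and **Gini importance** (total
impurity decrease per tree, averaged). `threshold_selection()` maximizes TSS
over a threshold grid, ties toward the lowest threshold. The
uplisted/not-uplisted model is exposed but emits an imbalance warning below
10% positives, reflecting its known failure mode.

## 6. The synthetic world

The generator is first-class, tested code, and its defaults are the stated
world, chosen once:

* 200 × 200 equal-area 1-km cells; smoothed-noise land-use patches (15%
  crop, 20% pasture), 12 settlements driving built/density/lights, and
  random polylines for 8 roads, 3 railways, 4 waterways (stored as
  distance rasters).
* Intensification 1993→2009 targets 30% of cells (the observed share of
  land with increased HFP is 30.8%): a spatially coherent subset undergoes
  land-use succession (bare → pasture → crop) and population growth, plus a
  few short road spurs. The realized share is emergent, not calibrated —
  the test asserts it lands within ±0.1 of the target across seeds.
* 300 species with blob-shaped ranges (log-normal radii, median 10 km);
  covariates drawn from documented distributions independent of the
  landscape; a 2 × 3 realm layout and a two-biome raster.
* Labels are planted on the clamped delta-extent at **HFP ≥ 3** (strict
  t = 2): `P(high-risk) = plogis(qlogis(0.31) + 2·z)` with z the
  standardized delta — a 31% baseline matching the observed high-risk share
  and a strong (standardized β = 2) effect. Category pairs realize the
  labels with fixed mixes (threatened-retained : uplisted = 8 : 1 within
  high-risk; LC-retained : downlisted = 60 : 1 within low-risk), echoing the
  observed 27.8% / 3.6% / 0.5% composition, and round-trip exactly through
  the classifier. The logistic link is a generator choice, not a claim
  about nature; the downstream classifier is link-agnostic.
* One root seed expands into named substreams (landscape / species /
  labels), so components can be regenerated independently and every output
  is byte-reproducible.

**What a green test establishes.** That the pipeline recovers a planted
threshold effect from data whose spatial structure, class imbalance and
category composition resemble the real analysis. **What it does not:** the
synthetic world has no real biogeography, no spatial covariate confounding
(covariates are independent of the landscape by construction), no
assessment error in category histories, and planar geometry without
projection effects. Global empirical numbers (shares of land intensified,
d = 0.43 at a threshold of 3, 82.9% CV accuracy and the published importance
ranking) depend on the real rasters and Red List data and are *not*
reproduced here; the tests check structural analogues only.

## 7. Numerical conventions and degenerate inputs

* Rounding: half-up for the integer index; shares reported to one decimal.
* Tie-breaks: lowest threshold wins in every argmax (effect profile,
  TSS selection, peak-change threshold); night-light ties take the lower
  decile; exact vote ties in the forest predict the reference class.
* Degenerate inputs: single-class label sets, all-nodata masks, empty
  geometries, all-tied rank tests and sub-fold sample sizes raise immediate
  errors naming the offending object; singleton groups and zero-variance
  effect sizes are flagged `NA` inside sweeps instead of aborting a whole
  run; degenerate label draws in the generator are resampled with a warning,
  bounded at 20 retries.
* Budget scaling in tests: the threshold-recovery acceptance check scans
  t = 0..5 with 200 trees and 5 folds (instead of 0..49 / 500 / 10) to stay
  inside the suite's time budget; the planted world itself is unchanged.

## 8. File formats

No geospatial raster package is assumed: rasters round-trip through the
plain-text Esri ASCII grid format (exact for integer grids, nodata
preserved), ranges through GeoJSON, tables through CSV with headers, reports
through JSON with a schema-version field. The pipeline manifest records
each stage's outputs with md5 checksums keyed by file name, so two runs of
the same configuration can be compared byte for byte regardless of location.
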