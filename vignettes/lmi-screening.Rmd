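---
title: "Threshold screening of low-mass-ion peak tables: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Threshold screening of low-mass-ion peak tables: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lmiscreen)
```

This vignette is the package's account of the screening method it
implements: the data model, the threshold-search semantics, the dual-ion
scores, the statistical gate, what the synthetic cohort generator does and
does not emulate, and the choices made where the method description leaves
room.

## Data model

A peak table is an ions × samples matrix of non-negative integrated peak
areas. An ion is identified by the *pair* (m/z, RT) — two ions can share a
mass value to four decimals and differ only in retention time, so m/z alone
is never a key. Samples are carried by name, never by column position, so
manifest joins are order-independent. The table carries a `scale` attribute
(`raw` or `log10`); every transform checks it, and files written by
`write_peak_table()` carry a `# scale=` marker so raw and transformed tables
cannot be confused on disk.

### The zero rule

All screening operates on common logarithms of peak areas. A peak area of
exactly 0 — a dropout, where the ion was not detected in a sample — is set
to 1 before the transform, so its log10 value is 0. The rule is literal:
only exact zeros are touched. Areas in (0, 1), which the synthetic generator
can produce, pass through `log10` and become negative. This matters for the
ratio-of-logs pair score, where a log area of exactly 0 makes a denominator
ion undefined (see below).

### Total-area-sums normalization

`normalize_total_area()` multiplies each sample column by one scalar so all
columns share the same total raw area. The method description fixes that the
totals become equal but not their common value; we use the **mean of the
original totals**, which preserves the overall magnitude of the table. It is
defined on the raw scale and applied before the log transform, because
"total peak area" is a raw-scale quantity. Two consequences are proven as
properties in the test suite: per-sample rank order of ions is unchanged,
and difference-method pair scores on all-positive tables are exactly
invariant (log(s·a) − log(s·b) = log a − log b), whereas ratio-of-logs
scores are not.

## Single-ion threshold search

For one ion and one two-class comparison, the per-sample log10 areas are
scanned with every threshold on a fixed grid:

- **Grid**: thresholds t = k·Δ for integer k, with Δ = 0.01 log10 units by
  default, spanning the pooled data range rounded outward to the grid.
  Thresholds outside the data range cannot improve the optimum, so wider
  bounds would only pad the tie set ends symmetrically-by-performance;
  the outward rounding keeps both extreme data points classifiable.
- **Comparator**: under orientation `positive_high` a sample is called
  positive iff its score is **strictly greater** than the threshold;
  `positive_low` uses strictly less. The method description never states the
  comparator; strict inequality makes the lowest grid point usable (a
  threshold at the maximal negative sample still classifies it correctly)
  and makes the perfect-threshold set a half-open interval on the score
  axis. The convention is centralized in `confusion_stats()` and its
  compiled mirror, so it can be flipped in one place.
- **Both orientations are always searched**: no direction is assumed a
  priori; the reported orientation is the better one, with ties resolved
  toward `positive_high` for determinism.
- **Objective**: sensitivity + specificity (the Youden-style sum). All grid
  thresholds attaining the maximum form the tie set; the reported
  `best_threshold` is their **arithmetic mean**, and the reported
  sensitivity/specificity are re-evaluated at that averaged threshold, so a
  reported result always reproduces exactly under `confusion_stats()`. The
  best sum found on the grid is carried separately as `optimum`. For a
  non-contiguous tie set the averaged threshold can in principle attain a
  smaller sum than `optimum`; this is a degenerate case that cannot occur
  under perfect discrimination (where the tie set is an interval), and both
  numbers are reported.
- **Gap**: when discrimination is perfect (optimum = 2), the width
  `max − min` of the tie set measures how robustly the classes separate and
  is the secondary ranking key. It is undefined otherwise (`NA`).

Ions are ranked by optimum, then gap (missing last), then Fisher's
discriminant ratio, then (mz, rt) — the last two keys are tie-breakers
invented for deterministic output.

**Fisher's discriminant ratio** is taken in its standard two-class form
(m₁ − m₂)² / (s₁² + s₂²) with n−1 sample variances; the source material
names the quantity without a formula. It is shift- and scale-invariant and
zero iff the class means coincide; zero pooled variance with distinct means
is reported as `Inf` with a warning rather than silently clamped.

### Numerical notes

The grid is generated as integer multiples of the increment
(`(k_lo:k_hi) * Δ`), never by accumulating additions, so the R reference and
the compiled sweep produce bit-identical thresholds. Grid-endpoint indices
use a 1e-9 slack inside `floor`/`ceiling` so that data values sitting
exactly on a grid line do not lose their boundary threshold to floating
error. The compiled pair-screen sweep buckets each score onto its first
covering grid index once and prefix-sums the buckets, rather than binary
searching at every grid point; bucket boundaries are fixed up against the
actual double comparisons, and the test suite asserts exact agreement with
brute-force grid evaluation (every grid point, direct elementwise
comparisons) on hundreds of random instances. One caveat is inherent:
properties like "shifting all scores by a grid multiple shifts the
threshold" hold only up to one increment, because a shifted score can land
on the other side of a grid line it previously coincided with.

## Dual-ion screening

Two pair scores are defined for an ordered pair (a, b) of distinct ions:

- `ratio_of_logs`: log₁₀(area_a) / log₁₀(area_b)
- `log_of_ratio`: log₁₀(area_a) − log₁₀(area_b) — the log of the raw-area
  ratio

Every ordered pair — N(N−1) of them, both role assignments of each
combination — receives the same grid threshold search, and pairs whose
sensitivity and specificity **both** reach 0.90 are selected. The selection
criterion "combined sensitivity/specificity > 90%" is read as *both ≥ 90%*:
every tabulated selected pair in the source material satisfies the stricter
reading, while "average > 90%" would admit asymmetric pairs never shown.
Both cut-offs are arguments, so the other reading is one call away.

For `ratio_of_logs`, a denominator log area of exactly 0 (raw area 1, or a
dropout after the zero rule) makes the score undefined. The default policy
**skips the ordered pair and counts it** — silently dropping samples would
change the effective n invisibly; a `drop_sample` policy is available and
skips only pairs where a whole class would empty. Skip counts are part of
the result and of the pipeline run manifest, and the bookkeeping identity
`screened + skipped = N(N−1)` is asserted in the tests.

For `log_of_ratio` the two orderings of a pair are mutually redundant — the
reversed pair with the opposite orientation has identical performance and a
negated threshold (when the orientation optimum ties, the deterministic
tie-break picks `positive_high` on both sides instead). The implementation
still screens and reports both orderings, per the ordered-pair convention;
the redundancy is verified as a property test rather than exploited, since
the exhaustive screen is already cheap at the scales used here.

Results stream through a fixed-size accumulator — only selected pairs are
kept, so memory is bounded by hits, not by N². The full-scale enumeration
count (45,205,452 ordered pairs for the 6,724-ion table) is obtained by a
streaming block counter without materializing anything.

## Group statistics

`compare_groups()` reproduces the gate used for the study's group
comparisons: Shapiro–Wilk normality per group, then an independent-samples
t-test if both groups pass at α = 0.05, otherwise the Mann–Whitney U test.
Choices where the description is silent, each with rationale:

- **Gate rule**: both groups must pass at 0.05 — the conventional reading of
  "normality was verified".
- **Welch by default**: "independent sample t test" does not assert equal
  variances; Welch is the safer default and `var_equal = TRUE` restores the
  pooled test.
- **Two-sided** p-values throughout.
- **Degenerate input**: a zero-variance group is treated as failing the gate
  (Shapiro–Wilk is undefined on constant data) and routed to Mann–Whitney;
  fully tied data, where the normal approximation degenerates, reports
  p = 1 — no evidence of a difference.
- Comparisons are run on **log10** areas, the scale on which all
  discriminative displays are drawn.

A simulation in the acceptance tests checks that the composite
gate-then-test procedure keeps its nominal type-I error: 1000 null
comparisons at n = 50 per class must reject at a rate within the binomial
3σ band around 5%.

## The synthetic cohort generator

Real raw data for this kind of screen is rarely shareable, so the generator
produces cohorts with exactly the statistical structure the analysis
assumes, plus a ground-truth registry so recovery can be scored without
re-deriving the plant:

- **Log-normal areas**: per-ion log10 areas are normal within group
  (baseline mean 4.0, sd 0.5 by default — peak areas around 10⁴ with a
  half-decade spread, a realistic magnitude for integrated LC-MS ion
  currents). All downstream analysis is logarithmic, so normality is placed
  on the analysis scale.
- **Null ions** are identically distributed across groups.
- **Planted singles** shift the mean by δ in the positive groups, with
  within-group sd σ.
- **Planted pairs** share a per-sample latent scale u ~ Normal(0, τ): ion 1
  is baseline + u + δ·[positive] + ε, ion 2 is baseline + u + ε. With
  τ ≫ σ each member ion is swamped by u and overlaps across classes, while
  the difference score is Normal(±δ, √2·σ) and separates — the mechanism by
  which markers can exist only as pairs.
- **Dropout** replaces raw areas with exact 0 at a configured rate,
  independently of intensity, after exponentiation — the simplest mechanism
  that exercises the zero rule downstream. Intensity-dependent dropout
  would be a configuration extension, not the default.
- Generation is a pure function of the seed; group sizes default to the
  study cohort layout (PC 51, BTC 39, control 100, CRC 100, OVC 30, PC_HRG
  21, BTC_HRG 25).

What the generator does **not** emulate: chromatographic peak shape,
isotopes and adducts, correlated ion families beyond the planted pairs,
intensity-dependent missingness, batch effects, or any relationship between
the synthetic (m/z, RT) labels — arbitrary unique coordinates — and
chemistry. Passing recovery tests therefore shows that the screening
machinery finds the structure it is designed to find at realistic sizes and
effect magnitudes; it does not validate the biological discriminators
reported for any real cohort, which depend on the original, non-deposited
peak table.

## Problem sizes in the tests

The test and acceptance workloads were sized to exercise every code path at
meaningful scale: oracle equivalence on 200+ random threshold-search
instances; planted-marker recovery on 50/50 cohorts with 500 null ions, 3
planted singles at δ/σ = 10 and one latent-scale pair at δ/σ = 14, τ/σ = 10,
across 20 seeds (≈ 254,520 ordered pairs screened per seed); 100-seed null
cohorts for the false-discovery check; and 1000 simulations for the type-I
error of the statistical gate. Full-scale pair screening of a 6,724-ion
table (≈ 45 million threshold searches) is supported by the compiled sweep
but exercised in the suite only as the streaming enumeration count.

## Known limitations

- The threshold grid is absolute (step 0.01 log10 units), not relative to
  the score spread; scores with very small dynamic range quantize onto few
  grid points. This mirrors the method being implemented rather than a
  statistical recommendation.
- No multiple-testing control is applied anywhere in the screen — the
  source procedure applies none — so at realistic N the pair screen's
  selected set must be read as candidates for validation, not discoveries.
- `ratio_of_logs` is not invariant under total-area normalization and is
  undefined at zero denominator log areas; the difference score is the more
  robust of the two and is the one with clean algebraic properties.
- Perfect-separation results at modest n are fragile by nature; the gap
  column quantifies robustness only within the observed cohort.
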