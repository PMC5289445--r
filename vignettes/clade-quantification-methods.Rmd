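---
title: "Methods: clade-specific qPCR quantification of coral symbiont communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clade-specific qPCR quantification of coral symbiont communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cladeqpcr)
```

## The measurement model

A clade-specific qPCR assay reports a cycle threshold Ct that is, over the
assay's log-linear range, an affine function of the log template amount:

    Ct = b + m · log10(q)

with slope `m` (Ct per decade, ≈ −3.32 for a perfectly doubling reaction)
and intercept `b` (the Ct of a single template copy). `cladeqpcr` treats
this line — the *standard curve* — as the calibration object for each of
the seven assays in the panel (clade-specific 28S sets for *Symbiodinium*
clades A–F, plus a coral-host 18S set). Everything downstream is either a
property of the line (efficiency, quantifiable range), an inversion of it
(copy-number estimation), or arithmetic on the inverted quantities
(S/H ratios, proportions, classification).

### Standard curves and efficiency

`fit_standard_curve()` regresses Ct on log10(quantity) by ordinary least
squares over a dilution series. Replicate Cts enter as independent
observations rather than being averaged first: the replicates carry real
information about the residual variance that the pairwise
coefficient-comparison t-tests need, and averaging would halve the degrees
of freedom for no gain in the point estimates.

Amplification efficiency is reported as

    E(%) = 100 × (−3.322) / m.

The direction of the ratio (expected over observed) is a deliberate
convention: with it, every curve in the package's supported parameter
range whose reaction is slightly *less* than perfectly doubling
(|m| > 3.322) lands just below 100%, which is how practitioners read
efficiency panels. Curves are also exchangeable with the exponential
parameterization `q = A·exp(−k·Ct)` sometimes used on printed plots via
`decay_to_slope()` (`m = −ln 10 / k`) and `decay_to_intercept()`
(`b = ln A / k`).

### Limit of quantification and the Ct ceiling

Absolute quantification of the 28S assays is reliable down to about 200
gene copies; below that the log-linear relation degrades. The LOQ is
therefore attached to each curve (default 200 copies for 28S assays,
configurable per assay) and mapped to a Ct ceiling
`ct_upper_limit = m·log10(LOQ) + b`. A well is only *quantified* when both
technical replicates sit at or below the ceiling; later Cts are reported
as `below_loq`, never converted to copies by the guarded path. (The
unguarded inversion remains available for deliberately examining trace
signals below the LOQ, which is how sub-200-copy detections are expressed
as approximate copy numbers.)

### Specificity

Cross-amplification between clade assays is scored with

    Sp(%) = 100 × (1 − Σ 2^−(Ctx − Cti))

summed over the off-target primer sets that amplify the target DNA at all;
a set that never amplifies contributes nothing. The 2^−ΔCt form expresses
the off-target signal as a fraction of the target signal under perfect
doubling: one cycle late = half the signal = 50 points, eight cycles late
≈ 0.4 points. An off-target amplifying *at or before* the target is
arithmetically allowed (Sp can go negative) but flagged as anomalous,
because it indicates a mislabeled panel rather than ordinary
cross-reactivity.

### Comparing curves

`compare_coefficients()` tests the difference of two fitted slopes or
intercepts with a pooled-residual-variance Student's t on
`n₁ + n₂ − 4` degrees of freedom — the textbook two-regression-lines test.
Noise-free (exactly collinear) inputs would make both the standard error
and the coefficient difference floating-point residue; both are floored at
10⁻¹⁰ of the coefficient scale so that self-comparisons give exactly
t = 0, p = 1 and noise-free parallel lines give an infinite intercept t
(reported with p = 0).

## Plate processing

**Replicate rule.** Each sample runs in duplicate on one plate; the two
Cts are averaged when |ΔCt| ≤ 1 (boundary inclusive). Larger disagreements
— including one amplifying and one censored replicate — are statuses
(`reprocess`), not values: at the bench such wells are re-run, which a
pipeline cannot do, so they are excluded from quantification and surfaced
in the QC log.

**Interplate calibration.** Every plate carries the same calibrator
template in triplicate per assay. The per-plate, per-assay offset is the
plate's mean calibrator Ct minus a reference Ct, and is subtracted from
every Ct on the plate (calibrators included, making calibration
idempotent). The reference policy is configurable: by default the first
plate processed defines the reference; when the calibrator's true Ct is
known (as with the simulator's `calibrator_reference` attribute), passing
it removes the offsets absolutely rather than relative to plate one.

**Positive calls.** A well is `positive` only when it passes replicate QC,
both replicates are at or below the assay's Ct ceiling, and the observed
melting temperature matches the expected amplicon Tm within tolerance.
The Tm tolerance defaults to 0.3 °C, chosen so that amplicon variants
about half a degree apart — such as the two C-clade melting profiles near
82.95 °C and 83.5 °C — are kept distinct while run-to-run Tm jitter
(sd ≈ 0.05 °C) is absorbed.

**Normalization and transform.** Host 18S units act as the per-sample
biomass denominator ("polyp units"): `S/H = clade copies / host units`.
No conversion from 18S units to polyp counts is attempted — none is
defined. Abundances are transformed as `ln(x) + 1` (the natural log first,
then +1, so a single copy maps to 1). The convention is pinned by the
worked values it must reproduce: 183 copies → 6.2095 (printed 6.21). The
companion value 26 → 4.2581 prints as 4.25 only if the underlying estimate
was ≈25.8 before rounding, so a ±0.01 tolerance accompanies comparisons of
this transform against printed two-decimal values.

## Community analysis

Per-colony proportions are each detected clade's share of the summed S/H
ratios (so they are invariant to any per-sample rescaling). A clade is
*dominant* above 5% and *background* at or below it; the boundary is
inclusive on the background side, and calls within ±0.1 percentage points
of the cut are flagged `near_boundary` — a sharp threshold on a continuous
proportion is sensitive to rounding, and published near-5% calls show
exactly this ambiguity. Patterns are alphabetically sorted clade strings
("ACD"); `enumerate_patterns()` generates all 2^k − 1 theoretical
patterns. Rounding policy for summaries follows the field's printing
habits: whole-sample shares as integers, pattern-group shares to one
decimal (`round_percent()`).

### DAPC

The ordination is a discriminant analysis of principal components:
features are centered, scaled (zero-variance features get unit scale), and
projected onto leading PCs; a linear discriminant analysis then maximizes
between-species over within-species variance in PC space. The default
number of retained PCs is the smallest set explaining ≥95% of total
variance, capped at the matrix rank and at n − G so the within-group
scatter stays invertible; the discriminant step solves the symmetric
whitened eigenproblem via a Cholesky factorization of the within-group
scatter, falling back to a small logged ridge (10⁻⁸ of the mean diagonal)
when that scatter is singular. Axis "percent of variance" is each
eigenvalue's share of the total discriminable variance, so the reported
percentages are non-increasing and sum to at most 100.

Features default to the `ln(x) + 1`-transformed per-clade 28S copy
numbers; absent clades enter as 0 by convention (the transform is
undefined at 0, and 0 is the natural "no signal" anchor one unit below a
single copy). S/H-ratio features are available through
`dapc_features(quant, "sh_ratio")`. Axis–clade associations are Pearson
correlations with `t = r·sqrt((n−2)/(1−r²))`; |r| within 10⁻¹² of 1
reports an infinite t and p = 0 rather than a meaninglessly huge finite
value.

## The synthetic plate generator

The generator exists so that the pipeline's accuracy claims are *measured*
rather than asserted: it draws colony-level communities with known copy
numbers, pushes them through the forward measurement model, and the test
suite checks that the pipeline recovers the truth.

What it emulates, and the defaults chosen once for the package:

* **Design**: 5 coral species across 5 reef-site labels, with colony
  counts 27/21/16/7/6; each species has a primary dominant clade, an
  optional co-dominant, and background clades that occur independently per
  colony with set probabilities at log-uniform relative abundances within
  [10⁻⁶, 5 × 10⁻²] — the span over which background clades are observed.
* **Scale**: total symbiont 28S copies per colony log10-uniform in
  [10⁵, 10^6.5]; host 18S units log10-uniform in [10^3.5, 10^4.5]. These
  put dominant clades comfortably above the LOQ and backgrounds on both
  sides of it, which is the regime the classifier must handle.
* **Measurement**: replicate Cts are
  `b + m·log10(copies) + plate offset + N(0, 0.15²)`; the 0.15-Ct noise sd
  is ordinary SYBR-green replicate scatter and the value around which the
  |ΔCt| ≤ 1 rule is comfortably loose. Plate offsets are N(0, 0.3²) —
  plate-level drift exists (it is why the calibrator is on every plate)
  but is not separately published, so a moderate value was fixed here.
  Curve constants per assay derive from printed exponential fits of the
  28S dilution series; Tm means for most assays are synthetic spacings
  ≥0.5 °C apart (only the two C-variant Tms are published).
* **Censoring**: wells whose noise-free expected Ct exceeds 40 cycles, or
  with zero template, are censored ("no amplification"). Censoring is
  monotone in template amount by construction.
* **Cross-amplification**: off by default; a per-assay ΔCt can make the
  off-target template amplify late, for exercising the Sp statistic.

What it deliberately does not model: fluorescence-level artifacts
(baselines, drift within a run), PCR inhibition, pipetting volume error
correlated across replicates, and contamination. Passing recovery tests
therefore demonstrate that the *analysis chain* is correct and stable
under the stated noise model — not that any bench protocol achieves that
noise model.

## Numerical and design choices

* Replicates enter curve fits unaveraged (df for the t-tests); sample
  replicates are averaged only after the |ΔCt| ≤ 1 rule.
* The 5% boundary is background-inclusive; exact-boundary and near-boundary
  calls are flagged rather than silently classified.
* Pattern strings are alphabetical — one canonical order, since mixed
  conventions ("BCD" vs "BA") cannot be round-tripped.
* The DAPC is computed in-package (whitened generalized eigenproblem) and
  cross-checked in the tests against both a dense eigensolver on the
  scatter matrices and `MASS::lda`'s singular values; correlations are
  dual-checked against `stats::cor.test`.
* Problem sizes in the test suite follow the emulated survey (77 colonies,
  7 assays, duplicate wells — about 700 wells per simulated run), with a
  1,000-survey Monte Carlo only for the background-occurrence expectation,
  where the binomial standard error must be small against the expectation
  of 2.

## Known limitations

* `reprocess` wells are dropped, not re-measured; heavy replicate
  disagreement therefore biases detection downward rather than adding
  noise.
* The first-plate calibrator reference makes all quantities exact only up
  to plate one's own offset; supply a known calibrator Ct to remove
  offsets absolutely.
* Cell-number estimation requires a per-clade cell standard curve; clades
  without one (e.g., no cultured isolate) report copies only.
* The DAPC is descriptive; no significance testing of group separation is
  attempted beyond per-axis correlation statistics.
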