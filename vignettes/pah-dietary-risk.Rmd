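---
title: "Dietary PAH exposure and cancer risk: models, calibration and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dietary PAH exposure and cancer risk: models, calibration and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pahrisk)
```

## The problem

Cereal-based baby foods are routinely screened for the 16 EPA-priority
polycyclic aromatic hydrocarbons (PAHs), carcinogenic process and
environmental contaminants. Such surveys produce a characteristic data
shape: a per-sample concentration table in µg/kg where a large fraction
of cells are non-detects ("nd", below the method's limit of detection),
summarized per product type, and then pushed through a toxic-equivalency
and intake model to answer one question — do the measured levels pose an
appreciable lifetime cancer risk to consumers?

`pahrisk` implements that chain end to end. This vignette documents the
models, the conventions chosen where the field leaves latitude, and what
the packaged synthetic data can and cannot tell you about real surveys.

## Models

**Censoring.** A measurement below the congener's LOD carries no numeric
value. Before any summarization every censored cell is substituted at
half the LOD (`impute_nondetects()`, rule `half_lod`). Zero, LOD and LOQ
substitutions are provided for sensitivity analysis, because half-LOD is
a convention, not an estimator with guarantees; under heavy censoring it
biases means toward LOD/2 regardless of the true distribution.

**Scores.** ΣPAH16 is the arithmetic sum of all 16 congeners; PAH4 is
the EU regulatory subset BaA + Ch + BbF + BaP. Compliance against the
1 µg/kg EU limits (BaP and PAH4 in processed cereal-based infant foods)
uses strict inequality: a group mean of exactly 1.0 µg/kg is flagged
non-compliant.

**Toxic equivalency.** Concentration profiles are collapsed to a
BaP-equivalent concentration

$$\mathrm{BEC} = \sum_{i=1}^{n} C_i \cdot \mathrm{TEF}_i,$$

linear in the concentrations and unit-preserving. The shipped default is
a Nisbet–LaGoy-style TEF set (BaP = DhA = 1; BaA, BbF, BkF, IP = 0.1;
A, Ch = 0.01; all others 0.001). TEF sets differ between agencies; any
named nonnegative vector with TEF(BaP) = 1 can be supplied.

**Intake.** The estimated daily intake in mg per kg body weight per day
is

$$\mathrm{EDI} = \frac{C \cdot IR \cdot ED \cdot EF}{BW \cdot AT},$$

with `C` in mg/kg food, `IR` the intake rate (kg/day), `EF` the exposure
frequency (days/year), `ED` the exposure duration (years), `BW` the body
weight (kg) and `AT` the averaging time (days). Summary tables work in
µg/kg; the conversion to mg/kg is explicit at the risk-model boundary
(`convert_concentration()`), never implicit.

**Risk.** The default, dimensionally consistent ILCR applies the oral
slope factor to a true dose:

$$\mathrm{ILCR} = \mathrm{EDI}(\mathrm{BEC}) \cdot SF
 = \frac{\mathrm{BEC} \cdot IR \cdot EF \cdot ED \cdot SF}{BW \cdot AT}.$$

An `as_published` mode evaluating `BEC·EF·ED·SF/(BW·AT)` — a form that
appears in parts of the survey literature but omits the intake rate and
is therefore a risk per concentration, not per dose — is retained for
comparison. Risk zones follow the conventional bands: below 10⁻⁶ safe;
10⁻⁶–10⁻⁴ intermediate; above 10⁻⁴ threshold risk exceeded; above 10⁻³
significant danger (upper bounds belong to their band). Separately,
`jecfa_flag()` trips when the BaP intake strictly exceeds
10 ng/kg bw/day.

## Default exposure parameters and their calibration

`SF = 7.3` (mg/kg/day)⁻¹ and `BW = 70` kg are the survey-stated values
(the adult body weight is kept verbatim even though baby-food consumers
are lighter; overriding `BW` rescales EDI and ILCR inversely). The
remaining parameters are not published as numbers in the source survey,
so the package ships a documented calibration:

| Parameter | Default | Unit | Role |
|---|---|---|---|
| IR | 0.013 | kg/day | daily baby-food intake |
| EF | 365 | days/year | exposure frequency |
| ED | 2 | years | exposure duration |
| BW | 70 | kg | body weight |
| AT | 730 | days | averaging time |
| SF | 7.3 | (mg/kg/day)⁻¹ | oral slope factor |

The combined factor `IR·EF·ED/(BW·AT)` equals 1.857×10⁻⁴ per day, the
median intake-per-unit-concentration implied by the survey's published
EDI percentile table (its median-EDI-to-concentration ratio is constant
across congeners to within rounding, which pins the factor without
pinning the individual parameters). Every value is overridable through
`exposure_params()`; only the combined factor matters for EDI and
dose-consistent ILCR.

## Monte Carlo design

`run_exposure_mc()` draws all inputs per iteration, truncates negative
concentration draws at zero, evaluates BEC/EDI/ILCR, and reports
empirical percentiles (order statistics with linear interpolation,
`quantile` type 7 — stable at the default 10⁴ iterations). Seeding is
mandatory in pipeline use (default 20220217); draws are taken under a
local RNG state so the caller's random stream is untouched.

The default stochastic structure places the variability on the shared
exposure factor — a lognormal intake rate with median `IR` and a
95th/50th percentile ratio of 1.5 — while concentrations enter as point
masses at the summary means. Two observations motivate this: the
survey's published percentile table shows an almost identical 95%/50%
ratio (≈1.5) for every congener, which is the signature of a shared
multiplicative factor rather than congener-specific concentration noise;
and with a shared factor the EDI ranking at every percentile provably
equals the concentration ranking, which is the structure the published
rank order exhibits. Lognormal concentration specs (moment-matched to
the group summaries) remain available via
`conc_specs(family = "lognormal")` for users who want concentration
uncertainty propagated as well; with them, high-CV congeners can
overtake at upper percentiles. Congeners never detected in any sample
are excluded from intake tables, matching survey practice; they still
enter the deterministic BEC at half-LOD.

Because the source survey's input distributions were never published,
its exact ILCR percentile value is not reproducible from printed inputs;
the package targets the reproducible structure instead — the intake
scale, the dispersion shape, the rank order, and the safe-zone
classification.

## The synthetic generator

`generate_dataset()` emulates the survey design: 9 cereal-based product
types × 2 brands assigned round-robin × duplicates = 36 samples, each
congener drawn around the packaged per-group targets and censored at the
LOD. Its defaults are the study conditions; `n_per_group` is exposed as
a parameter because the per-group sample count is inferred from the
survey's total, not stated.

The default noise family is a normal truncated at zero, parameterized so
that the *post-truncation* mean equals the target mean (the parent mean
is solved by root-finding, with the parent sd set to the target sd).
A naive parent-(mean, sd) parameterization is biased upward for cells
whose mean is within about one sd of zero — several low-level congeners
in the targets — and would fail its own recovery checks. Matching the
truncated mean keeps the generator unbiased for the quantity the
summaries estimate; the achieved sd is slightly below the target sd
(conservative for SE-based checks). One target cell has a coefficient of
variation above 1, which no zero-truncated normal can reach; its mean is
still matched exactly and its dispersion is the feasible maximum. A
lognormal family (which reaches any CV) is available as an alternative.

Two target cells whose printed group mean equals exactly half the LOD
while the printed range is entirely non-detect are encoded as
all-non-detect; half-LOD substitution regenerates the printed mean.

What the generator does **not** emulate: analytical recovery and matrix
effects, instrument drift, between-duplicate correlation, and any
distributional shape information beyond the first two moments — the
published summaries contain none. Passing recovery tests therefore shows
the pipeline is statistically faithful to the published summary
structure, not that it would reproduce raw-data reanalyses.

## Clustering conventions

The heat-map feature matrix holds group mean concentrations for the 16
congeners plus ΣPAH16 and PAH4 (rows) across product types (columns).
Rows are standardized to zero mean and unit variance (the usual heat-map
preprocessing); congeners pinned at half-LOD in every group have zero
variance, an undefined correlation, and are dropped with a message.
The dissimilarity is the Pearson correlation distance `d = 1 − r`
(not `1 − |r|`), invariant to affine rescaling of each profile, and the
tree is average linkage (UPGMA) via `stats::hclust`; equal-height merge
ties follow `hclust`'s ordering (the packaged matrix has none). Cutting
at k = 3 on the packaged targets places BbF, BaP and PAH4 in one
cluster — the co-movement of the marker carcinogen with the regulatory
sum — though three-cluster memberships are sensitive to preprocessing
choices and should be read qualitatively.

## Numerical conventions and degenerate inputs

* Standard deviations of single-observation (or all-identical) groups
  are reported as 0 rather than NA.
* The overall summary row aggregates group summaries, not pooled
  samples: unweighted mean of group means, sd across group means,
  extrema of group minima/maxima. This is how survey-level tables are
  constructed when raw data are unavailable, and it is the convention
  under which the packaged targets reproduce their published overall
  statistics.
* One-way ANOVA is the classical equal-variance F
  (`stats::oneway.test`); zero-total-variance inputs return F = 0,
  p = 1 by convention, and groups of size 1 are rejected.
* `BEC = 0` leaves contribution fractions undefined; they are returned
  as NA with `contributions_defined = FALSE`.
* Truncation in distribution specs is enforced by rejection sampling
  with a bounded number of rounds; bounds excluding essentially all mass
  raise an error.
* Ranking ties break by panel order, deterministically.

## Problem sizes used by the test suite

The suite exercises the generator at the study scale (4 samples per
group) and at recovery scale (200–500 per group); Monte Carlo checks run
at 10⁴ iterations with smaller runs for degeneracy and reproducibility
checks; the ANOVA type-I calibration uses 1000 null replicates at the
study layout (9 × 4); the UPGMA implementation is checked exhaustively
against a brute-force oracle for all sizes up to 6 leaves. These sizes
make the full suite run in well under a minute while keeping every
statistical check adequately powered.

## Known limitations

* Half-LOD substitution is a convention; censored maximum-likelihood or
  Kaplan–Meier-type estimators are out of scope.
* The exposure calibration reproduces a combined factor, not the
  individual IR/EF/ED/AT values, which are not identifiable from the
  published summaries.
* Dermal and inhalation routes, and non-carcinogenic hazard quotients,
  are not modelled.
* Cluster memberships at k = 3 are qualitative; leaf order and exact
  memberships depend on preprocessing.
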