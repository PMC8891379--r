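# pahrisk

Dietary exposure and cancer-risk assessment for polycyclic aromatic
hydrocarbons (PAHs) in cereal-based infant foods.

Surveys of the 16 EPA-priority PAH congeners in baby food report
left-censored concentration tables (many cells are "nd", below the
analytical limit of detection) summarized per product type, and turn them
into health-risk statements via toxic-equivalency scoring and intake
modelling. `pahrisk` implements that full analysis chain as a tested,
reusable pipeline for analysts working with such surveys:

* **Censored-data handling** — non-detects are substituted at half the
  congener's LOD (the survey convention; zero/LOD/LOQ rules are available
  for sensitivity analysis).
* **Group summaries and compliance** — per-product-type mean/SD/min/max
  per congener, the total burden ΣPAH16, the EU regulatory sum
  PAH4 = BaA + Ch + BbF + BaP, strict-inequality checks against the
  1 µg/kg EU limits for BaP and PAH4 in processed cereal-based infant
  foods, and one-way ANOVA across product types.
* **Risk equations** — BaP-equivalent concentration
  `BEC = Σᵢ Cᵢ·TEFᵢ`, estimated daily intake
  `EDI = C·IR·ED·EF / (BW·AT)` (mg per kg body weight per day), and
  incremental lifetime cancer risk `ILCR = EDI(BEC)·SF` with the oral
  slope factor SF = 7.3 (mg/kg/day)⁻¹, classified into the conventional
  zones (safe < 10⁻⁶; threshold risk above 10⁻⁴; significant danger
  above 10⁻³), plus the JECFA 10 ng/kg bw/day BaP-intake flag.
* **Monte Carlo uncertainty** — distribution specs for every input,
  percentile tables (5/50/75/95%) for EDI and ILCR, rank ordering, and a
  convergence ladder.
* **Synthetic data** — a generator that emulates the survey design
  (9 product types × 2 brands × duplicates = 36 samples) from packaged
  per-group targets, with censoring at the LODs, so every stage is
  testable without the unpublished raw data.
* **Clustering** — congener/product-type heat maps with Pearson
  correlation distance (d = 1 − r) and average linkage (UPGMA).

## Worked example

```r
library(pahrisk)

# published per-product-type targets -> summary table with overall row
smry <- summary_from_targets()
subset(smry, product_type == "overall" &
             statistic %in% c("sigma_pah16", "pah4", "BaP"))
#>   product_type   statistic  mean    sd  min  max
#>   overall       BaP         0.292 0.146 0.11 0.58
#>   overall       sigma_pah16 3.73  0.756 2.70 5.54
#>   overall       pah4        0.722 0.194 0.37 0.99

extreme_groups(smry, "sigma_pah16")
#> $max_group "mixed 5 cereal-based"        $max_value 5.06
#> $min_group "mixed wheat and date-based"  $min_value 3.03

# deterministic risk chain on the overall concentration profile
res <- assess_risk(summary_concentrations(smry, unit = "ug/kg"))
res
#> <risk_result>
#>   BEC: 0.408 ug/kg BaP-eq
#>   top contributor: BaP (71.6%)
#>   ILCR (dose_consistent): 5.532e-07 [safe]
#>   JECFA BaP-intake exceeded: FALSE

# probabilistic intake: 10^4 iterations, seeded
mc <- run_exposure_mc(conc_specs(smry), cfg = mc_config(seed = 20220217))
mc$ilcr
#>          p5         p50         p75         p95
#> 3.642e-07   5.463e-07   6.419e-07   8.114e-07
rank_by_percentile(mc$edi, 95)
#> [1] "P"  "F"  "BkF" "Ch" "BaP" "A" "Ace" "NA" "Pa" "BbF" "DhA" "IP"
```

The BEC of ~0.41 µg/kg BaP-equivalents is dominated by BaP itself
(~72% under the default TEF set); the 95th-percentile ILCR of ~8×10⁻⁷
sits below the 10⁻⁶ safe-zone boundary, i.e. the surveyed products pose
no appreciable carcinogenic risk under the default exposure scenario.
Pyrene leads the intake ranking, fluorene second, with DhA and IP at the
bottom.

A full report bundle (summary tables, compliance, risk JSON, percentile
tables, heat map with dendrograms, metadata) is written by:

```r
render_report("report", smry, risk = res, mc = mc, seed = 20220217)
```

## Documentation

The methods vignette (`vignettes/pah-dietary-risk.Rmd`) describes the
model, its assumptions, the calibration of the default exposure
parameters, what the synthetic generator does and does not emulate, and
the package's numerical conventions.
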