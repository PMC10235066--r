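# pacarbon

Counterfactual carbon accounting for protected areas.

Protected areas (PAs) tend to sit on land that would carry high biomass
with or without protection, so the carbon they *add* cannot be read off a
raw protected-vs-unprotected comparison. `pacarbon` implements the
standard impact-evaluation answer at 1-km scale: match every protected
cell to an ecologically similar unprotected counterfactual, difference
their lidar-derived aboveground carbon densities, attribute the
difference to avoided deforestation or degradation using forest-loss
records, and expand it over the PA estate to totals with uncertainty.

It is written for conservation and remote-sensing scientists who want a
fully testable, self-contained version of this analysis: a synthetic
landscape generator with known ground truth stands in for the lidar shot
tables, PA polygons and loss masks, so every stage can be verified by
parameter recovery.

## The method

For protected cell *i* with matched counterfactual *c(i)*, the paired
difference of mean carbon density is

    d_i = AGCD_i − AGCD_c(i)        (Mg C/ha, AGCD = 0.49 · AGBD)

Matching is exact on land cover, country, ecoregion and biome, and
nearest-neighbour without replacement on a logistic propensity score
e(x) = P(protected | x) over ten standardized quantitative covariates,
restricted to common support with a caliper of 0.2·SD(logit e). Controls
must lie more than 10 km from any PA boundary; cells need at least 5
quality-filtered shots (quality flag 1, sensitivity ≥ 0.95). Within each
country × biome stratum *s*, the additionally preserved carbon is

    A_s = mean(d_i) · area_s · 100 · 1e-9     (Gt, area in km²)
    SE(A_s) = sd(d_i)/√n_s · area_s · 100 · 1e-9

with continent × biome fallback for strata without pairs, and sums (with
quadrature-combined SEs) to country, continent, biome and global scales.
Each matched PA is further classified into five effectiveness classes
(avoided deforestation, enhanced stocks, no additionality, encroachment,
degradation) from its AGBD difference (±2.5 and 5 Mg/ha thresholds) and
the loss fractions inside vs outside, and a year-2000 baseline regression
on PA age tests for preferential placement.

## Worked example

The `analysis/` scripts run the whole study on the default synthetic
world (100 × 100 km, 20 PAs, true effect +10 Mg/ha AGBD = 4.9 Mg C/ha,
loss rates 1% inside vs 5% outside):

```sh
Rscript analysis/01_simulate_landscape.R
Rscript analysis/02_process_footprints.R
Rscript analysis/03_match.R
Rscript analysis/04_estimate.R
Rscript analysis/05_attribute_loss.R
Rscript analysis/06_baseline_check.R
Rscript analysis/07_published_value_checks.R
```

Stage 4 prints (seed 1):

```
global mean matched difference: 5.03 +/- 1.00 Mg C/ha over 282 pairs
naive (unmatched) difference:   9.05 Mg C/ha
additionally preserved carbon:  0.00023 +/- 0.00005 Gt over 450 km2
design value of the protection effect: 4.90 Mg C/ha
```

The matched estimate recovers the designed 4.9 Mg C/ha within one
standard error, while the naive contrast is nearly twice the truth —
that gap is exactly the placement confounding the matching removes.
Stage 5 attributes the effect: loss fractions are 0.009 inside PAs vs
0.046 in counterfactuals, and avoided deforestation is the modal class
(14 of 19 classified PAs). Stage 6 shows older PAs carry a +3.2 Mg C/ha
year-2000 baseline difference against +0.3 for recently designated ones —
the accrued-growth signature, not preferential placement. Stage 7 pushes
the published summary tables through the same arithmetic: the six
continental values sum to the printed 9.64 Gt global total, 61.4/235 Gt
gives the printed 26% protected share, and 3.54/9.65 Gt gives the printed
36.6% top-country share.

Equivalently in R:

```r
library(pacarbon)
run <- run_pipeline(run_config(seed = 1))
run$estimates$globe_pairs   # matched difference and SE
run$shares                  # five-class attribution
```

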