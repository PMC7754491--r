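# plastevol

Does phenotypic plasticity evolve to lower levels when the environment
fluctuates less predictably? Long-term selection experiments with the
halotolerant microalga *Dunaliella salina* address this by evolving replicate
lines under randomly fluctuating salinity with controlled predictability, then
assaying each evolved line's morphological plasticity by flow cytometry.
`plastevol` implements that full analysis chain as a tested, reusable R
package — for experimental evolutionists and quantitative ecologists who want
to simulate such designs, analyse cytometry-derived morphology tables, or
reuse the resampling machinery.

## What it computes

**Environment.** Each line's salinity history is a stationary AR1 process

S<sub>t+1</sub> = μ + ρ(S<sub>t</sub> − μ) + ε<sub>t</sub>,  ε<sub>t</sub> ~ N(0, σ²(1 − ρ²)),

with μ = 2.4 M NaCl, σ = 1 M shared across autocorrelation treatments
(ρ̄ ∈ {−0.5, 0, 0.5, 0.9}). Environmental predictability is ρ², the share of
temporal variance explained by the previous salinity; each line's *realized*
ρ² is estimated from its own finite series. `transfer_recipe()` converts
consecutive salinities into bench volumes of 0 M / 4.8 M stock media under
20% serial dilution.

**Phenotypes.** Per-cell event tables (FSC, SSC, Red-B, Yellow-B, FSC-W on
the instrument's log scale) are gated for live algae on the Red-B/Yellow-B
cytogram, cleaned of doublets by pulse width, bead-calibrated per assay
salinity, and balanced by subsampling up to 150 cells per condition. A
synthetic-data module generates complete studies with known structure, so the
whole chain is testable without any data download.

**Inference.** Morphological variation is partitioned by redundancy analysis
(RDA): sequential multivariate R² per explanatory term (strain, growth rate,
day, assay salinity, ρ², and their interactions), with ANOVA-like permutation
tests (999 randomisations). A line's **degree of plasticity** is the Euclidean
distance between its mean bead-corrected morphology vectors at 0.8 M vs 4.0 M.
The distance is regressed on ρ², and significance is assessed by a
hierarchical nonparametric bootstrap: resample lines with replacement, then
150 cells per line and salinity with replacement, recompute all distances and
the slope, 1000 times.

## Worked example

```r
library(plastevol)

design <- generate_design(n_fluct = 8, n_const = 2, seed = 1)
study  <- generate_study(design, days = 10, salinities = c(0.8, 4.0),
                         n_events = 400, seed = 2)

cells <- study$events |>
  gate_alive() |>
  remove_doublets() |>
  bead_correct(study$beads) |>
  subsample_events(cap = 150, seed = 3)

boot <- hierarchical_bootstrap(cells, design, day = 10, B = 1000, seed = 4)
boot
#> Hierarchical bootstrap (1000 replicates, 150 cells/line/salinity, day 10)
#>   observed slope 1.8219 (R2 0.944)
#>   P(slope <= 0) = 0  [P(slope > 0) = 1]

glance(boot)
#> # A tibble: 1 × 8
#>   slope intercept r.squared slope_boot_mean p_slope_le_0 p_slope_gt_0     B
#>   <dbl>     <dbl>     <dbl>           <dbl>        <dbl>        <dbl> <dbl>
#> 1  1.82     0.521     0.944            1.87            0            1  1000

tidy(boot)
#> # A tibble: 8 × 4
#>   line_id predictability distance     se
#>   <chr>            <dbl>    <dbl>  <dbl>
#> 1 L01             0.223     1.07  0.0346
#> 2 L02             0.361     1.32  0.0341
#> 3 L03             0.0117    0.347 0.0353
#> 4 L04             0.0145    0.553 0.0346
#> # ℹ 4 more rows
```

The observed slope (1.82 distance units per unit ρ²) says lines that evolved
under more predictable salinity kept larger plastic responses; no bootstrap
replicate produced a non-positive slope, so the one-sided significance level
is at its floor. The generator built these data with slope 2 and per-line
noise, so the estimate is recovering the truth within its bootstrap error.
`autoplot(boot)` draws the per-line distances with the observed and replicate
regression lines; `run_study(study_config(...))` chains every stage (including
RDA partitioning and the per-day slope profile) into one seeded, reproducible
bundle summarised by `report()`.

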