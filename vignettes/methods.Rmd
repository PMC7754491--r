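---
title: "Models and methods behind plastevol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind plastevol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastevol)
```

`plastevol` implements the analysis chain of an experimental-evolution study
of morphological plasticity in a halotolerant microalga: simulated stochastic
salinity regimes, flow-cytometry preprocessing, multivariate variation
partitioning, and a resampling-based test of whether the degree of plasticity
tracks environmental predictability. This vignette explains each model, its
assumptions, the tunable parameters, and the design choices that were
genuinely open.

## The salinity environment

Each evolving line experiences salinity as a stationary first-order
autoregressive process across serial transfers,

$$S_{t+1} = \mu + \rho\,(S_t - \mu) + \varepsilon_t, \qquad
\varepsilon_t \sim N\!\big(0,\ \sigma^2 (1-\rho^2)\big),$$

with stationary mean $\mu = 2.4$ M NaCl and stationary standard deviation
$\sigma = 1$ M. Scaling the innovation variance by $1-\rho^2$ is the
parameterisation that makes all autocorrelation treatments
($\bar\rho \in \{-0.5, 0, 0.5, 0.9\}$) share the same long-run mean *and*
variance, so treatments differ only in predictability
$\rho^2$ — the proportion of temporal variance explained by the previous
value. Two consequences worth noting:

* The first value is drawn from the stationary distribution $N(\mu,\sigma^2)$
  rather than pinned at $\mu$, so realized moments are unbiased at finite
  series length.
* $\bar\rho = -0.5$ and $+0.5$ lines share $\rho^2 = 0.25$ while experiencing
  very different magnitudes of change per transfer; the analysis treats them
  identically, which is itself a testable design assumption.

Because a 139-transfer realization is finite, each line's *realized*
autocorrelation (Pearson correlation of consecutive salinities,
`realized_autocorrelation()`) scatters around its treatment target; the
analysis always uses the realized $\rho^2$ as a continuous covariate.

Series are generated **unclipped**. Physical feasibility — a transfer retains
20% of the culture and adds 800 µl of medium mixed from 0 M and 4.8 M
stocks — is enforced only by `transfer_recipe()`, which solves the mass
balance $m = (s_{target} - f\,s_{pre})/(1-f)$, clamps $m$ to $[0, 4.8]$ M when
needed, recomputes the achieved salinity and flags the transfer infeasible.
Clamp-and-flag (rather than redrawing or reflecting the AR1 draw) keeps the
statistical targets of the simulated process undistorted and makes the
rare truncation events visible to the user; how the original bench protocol
handled unreachable targets is not something the recipe model needs to decide.
Whether "20% dilution into 800 µl" means a 200 µl carry-over in a 1000 µl
final volume is likewise ambiguous; the retained fraction is an explicit
argument (default 0.2) so either reading is one call away.

## The synthetic study generator

The generator (`generator_params()`, `generate_study()`) emulates the
statistical structure the downstream analysis assumes, with every choice a
named, documented parameter:

* **Morphology.** Alive singlets are Gaussian on three log-scale channels
  (FSC, SSC, Red-B) around
  `baseline + ontogeny(day) ± magnitude/2 · salinity_effect`. The salinity
  response acts along a fixed direction `(-0.6, 0, -0.8)` — smaller cells with
  less chlorophyll at high salinity — of unit norm, so the expected
  low-vs-high Euclidean distance *is* the magnitude.
* **Plasticity structure.** A line's magnitude is
  $(a + b\,\rho^2_i + \delta_i)\cdot g_{phase(day)}$ with intercept $a = 0.5$,
  slope $b = 2$ (log units), and a per-line deviation
  $\delta_i \sim N(0, 0.1^2)$. The deviation is essential, not cosmetic:
  evolved lines are biological replicates, and the hierarchical bootstrap's
  line-resampling level is only meaningful (and only calibrated) when lines
  genuinely vary beyond cell-sampling noise. Constant-regime lines get the
  magnitude of a $\rho^2 = 0.7$ line, encoding their observed similarity to
  high-predictability lines.
* **Ontogeny.** The day-indexed offset table traces a closed loop in channel
  space (radius 0.5 log units over days 0–10), so start and end morphologies
  sit near each other while mid-assay days are displaced. A day-indexed table
  was chosen over a dynamical model because the loop's shape, not its
  mechanism, is what the centroid-trajectory analysis consumes.
* **Growth phases.** Plasticity is multiplied by a per-phase gain
  (lag 1, exponential 0.25, stationary 1), emulating the observation that
  plasticity is weakest during rapid division. The generator carries an
  explicit day→phase map (days 1–2 lag, 3–4 exponential, 5–10 stationary)
  rather than deriving phases from its own logistic growth curve: the
  closed-form logistic $N(t) = K N_0 e^{rt}/(K + N_0(e^{rt}-1))$ has a
  monotonically decreasing discrete per-capita rate, so it cannot by itself
  delay the highest-rate block past day 1. The map and the curve are
  independent knobs; `classify_phases()` remains the data-driven labelling.
* **Contamination and optics.** Events are a mixture of alive singlets, dead
  cells (low Red-B relative to Yellow-B), debris (low everything) and
  doublets (alive morphology, +log₁₀2 per channel, wide FSC-W), at fractions
  0.10 / 0.05 / 0.05. All channels are shifted by a per-salinity
  `bead_offsets` vector that bead calibration must cancel. Event counts per
  condition follow the density-limited acquisition rule (density × 35.4 µl,
  bounded below by ~150–160 and above by the cytometer's 5000-event stop).

What the generator does **not** emulate: osmotic physiology and its time
scales, genetic polymorphism within lines, instrument drift between assay
days, non-Gaussian channel distributions, or correlated channel noise.
Passing tests therefore demonstrate that the pipeline recovers the structure
it assumes — parameter recovery, calibration, invariances — not that the
biological conclusions of any particular real dataset are correct.

## Gating and calibration

The live/dead cytogram gate is formalised as two log-scale thresholds
(minimum Red-B, minimum Red-B − Yellow-B; defaults 3.2 and 0.5) and the
doublet cut as one FSC-W threshold (2.75). Real instruments need these set
per dataset; the defaults are calibrated to better than 99% class separation
on the generator and are deliberately plain, inspectable numbers rather than
learned gates. Bead correction subtracts the per-salinity bead channel means
from each cell, removing medium-density optical effects; all analysis stays
on log-scale instrument units, with no linearisation and no channel
standardisation (channels already share a scale after bead correction).
Subsampling to ≤150 cells per condition balances the design against
density-limited early days; it is uniform without replacement and seeded.

## Variation partitioning

RDA on a three-channel response is multivariate least squares. The
implementation builds, term by term in table order, an orthonormal basis
increment for each term's centred columns given all earlier terms (QR with
pivoting; a collinear term has its df reduced with a warning). Term $k$'s
share is $R^2_k = SS_k / SS_{total}$ and its pseudo-F is
$(SS_k/df_k)/(SS_{res}/df_{res})$. Significance uses free permutation of
response rows, recomputing the full decomposition each time, with
$p = (1 + \#\{F^* \ge F\})/(1 + n_{perm})$; 999 permutations give a p-value
floor of 0.001. Residual permutation under the full model (ter Braak) is
available behind the `permute` flag.

Choices that were genuinely open:

* **Sequential vs marginal attribution.** The partitioning defaults to
  sequential in the printed term order (strain, growth rate, day, salinity,
  $\rho^2$, then interactions); `marginal = TRUE` adds each term's partial
  $R^2$ given all others, needed when one wants the effect of time *beyond*
  growth rate.
* **Day 0** (pre-transfer acclimation) is excluded from partitioning, which
  is what gives the day factor 9 df for a 10-day assay.
* **Growth rate per cell row** is the condition-level (line × salinity × day)
  per-capita rate broadcast to every cell of that condition; cells carry no
  individual growth information.

The test suite proves the decomposition exactly equal (to $10^{-10}$) to a
brute-force per-column ANOVA oracle on small matrices, conservation
($\sum R^2 = 1$), order-invariance of the total explained share, agreement
with `vegan::rda`'s term variances, and uniformity of the permutation p under
a null predictor.

## Degree of plasticity and the hierarchical bootstrap

A line's degree of plasticity is the Euclidean distance between its mean
bead-corrected channel vectors at 0.8 M and 4.0 M — raw channel space, not
PCA scores, not standardised, because the distance should inherit the
channels' common physical scale and stay invariant to the common shifts that
bead correction introduces. The distance is regressed on realized $\rho^2$
across fluctuating lines only (constant lines have no $\rho^2$; they are
summarised separately and enter only group comparisons).

Inference mirrors the data's nesting: each of $B = 1000$ replicates redraws
the 32 lines with replacement, then 150 cells with replacement per drawn line
and salinity, recomputes every distance and the OLS slope. Conventions worth
stating:

* `p_one_sided` is the proportion of replicate slopes ≤ 0 (small values
  support plasticity increasing with predictability); the complementary
  proportion > 0 is reported alongside, since either convention is a
  legitimate reading of "proportion of simulations supporting the sign".
* A line with fewer than 150 cells on a day is still resampled to 150 — the
  fixed-n scheme forces with-replacement upsampling.
* A replicate that happens to redraw a single line has no $\rho^2$ spread and
  an undefined slope; such replicates are excluded with a warning (they are
  vanishingly rare at 32 lines and only matter in toy designs).
* The group-comparison test (`compare_groups()`) reuses the same two-level
  resampling within each group and doubles the smaller tail probability of
  the replicate difference distribution.

## Problem sizes and numerical choices

The package's statistical guarantees are exercised at sizes chosen to make
the checks decisive yet quick: stationarity and realized-autocorrelation
recovery on $10^5$-step series (tolerance ±0.02, where the Monte-Carlo error
of a lag-1 correlation is ~0.003); permutation calibration over 200 simulated
null datasets at 999 permutations each; bootstrap type-I error over 200
fresh end-to-end studies of 8 lines × 150 cells with the generator slope set
to zero (rejection rate compared against the exact binomial 99% band around
0.05); slope recovery over 20 studies at the full 32-line design. Sub-seeds
for every stage derive from one root seed through a fixed integer counter, so
whole-study runs are bitwise reproducible and any single stage can be rerun
standalone.

Degenerate inputs are handled explicitly rather than silently: zero-variance
salinity series are flagged and excluded from autocorrelation, empty gates
warn, a constant response errors in the partition, zero $\rho^2$ variance
errors in the regression, and an all-identical bootstrap is flagged
degenerate.

## Known limitations

* The AR1 model has no drift, seasonality or ARMA structure, and recipes
  ignore evaporation and pipetting error.
* Gating is two fixed thresholds; real cytograms may need curved or learned
  gates, and no spectral compensation is attempted.
* The per-phase plasticity gain is piecewise constant; real
  growth-phase dependence is presumably smooth in growth rate.
* FCS binary ingest is out of scope: the package reads the plain CSV event
  dialect, and list-mode exports must be converted upstream.
* Permutation tests permute rows freely and thus assume exchangeable cells;
  with strong within-line correlation the RDA p-values are anti-conservative
  (the hierarchical bootstrap, which respects the nesting, is the primary
  inference for the plasticity question).
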