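---
title: "Modelling cortical neurogenesis and the gyrencephaly threshold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling cortical neurogenesis and the gyrencephaly threshold}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cortigen)
```

## The model

Adult cortical neuron number is modelled as the output of a deterministic,
discrete-cycle process. At the onset of neurogenesis a species has a pool of
`P` neuroepithelial founder cells lining the ventricle. Each founder commits
to one of seven progenitor lineages; the proportional occurrence of the
lineages is the species' *neurogenic program*. Every lineage runs from the
first to the last day of the neurogenic period, completing
`k = floor(neurogenic_days * 24 / cell_cycle_hours)` whole cell cycles
(divisions are discrete events, so the fractional remainder is dropped).
The predicted count at the termination of neurogenesis is

    N = P * sum_i p_i * L_i(k),

where `L_i(k)` is the cumulative neuron output per founder of lineage `i`.
Because postnatal apoptosis removes roughly a third of the neurons present
at the end of neurogenesis, model output is compared against 1.5-fold the
adult count (`apoptosis_adjust()`); this basis is switchable
(`predict_table(..., adjust = FALSE)`).

### The seven lineages

The lineage series are derived from explicit division rules and validated
in the test suite against an exhaustive agent-level simulation of the same
rules (exact equality for all `k <= 12`):

* **Lineage 1** — the apical radial glia (aRG) self-renews each cycle and
  directly produces one neuron: `L1(k) = k`.
* **Lineage 2** — the aRG produces one neurogenic basal intermediate
  progenitor (n-bIP) per cycle; each n-bIP divides once into two neurons a
  cycle later: `L2(k) = 2(k - 1)`.
* **Lineage 3** — the aRG produces one basal radial glia (bRG) per cycle;
  each bRG self-renews and produces one neuron per cycle:
  `L3(k) = k(k - 1)/2`, quadratic in the cycle count.
* **Lineages 4–7** — the aRG produces one bRG per cycle; each bRG emits,
  per cycle, one proliferative basal progenitor (p-bIP) seed of
  amplification depth `d = 1..4`. A depth-`d` seed doubles for `d` cycles
  and the resulting `2^d` cells each divide terminally into two neurons:
  `L_{3+d}(k) = 2^(d+1) * C(k-d-1, 2)`. Lineage 5 carries a convergence
  constant `c = 0.989` multiplying its series.

A depth-`d` cascade needs `d + 1` cycles of pipeline fill, so lineage
`3 + d` overtakes every asymmetric lineage from `k = d + 4` onward (all
four from `k = 8`); before that point a deep cascade has produced nothing.
This fill-in behaviour is asserted as a property test.

The published per-species parameter set (17 species; gestation and
neurogenic periods, observed adult neuron counts, founder pools, averaged
cell-cycle lengths) ships as `species_table()`, and the best-fit lineage
proportions per taxon as `builtin_programs()`. Mouse-type programs use
lineages 1–3 only; human-type programs drop lineage 1 and place 40% of
founders on the proliferative lineages 4–7.

### What the reconstruction can and cannot reproduce

The closed-form series behind the published curves are not recoverable
from the source material, so the division rules above are *the* model
here, stated and tested as such. Running the shipped parameter table
through the model reproduces the qualitative structure — human-program
predictions exceed mouse-program predictions for every species, the mouse
program grossly underestimates large brains and the human program grossly
overestimates small ones, and trade-off inversions give fold-changes of
the published order — but not the printed per-species deviation bounds.
That failure is not a tuning problem: the printed parameter table is
internally inconsistent with *any* common monotone lineage series. Two
examples, visible by direct arithmetic on the table: the orangutan
requires a higher per-founder output after 55 cycles than the human does
after 59 under the same program, and the agouti (58 cycles) requires
essentially the same per-founder output as the tupaia (24 cycles) while
the capybara (71 cycles, same program) requires 55% more. Cumulative
output cannot decrease in the cycle count, so no calibration of the
series can satisfy those bounds simultaneously. The acceptance tests
assert the printed bounds anyway and are expected to fail against this
parameter set; the package reports the honestly computed values.

## Program inference and trade-offs

`enumerate_programs()` generates all proportion vectors on a grid (default
step 0.05, matching the granularity of the published program estimates),
optionally with lineages constrained to zero; `best_fit_program()`
minimises the percent deviation against the apoptosis-adjusted count, with
ties broken towards the least proliferative program and then towards
weight on lower-numbered lineages (parsimony of proliferative potential,
deterministic output). On zero-noise synthetic species the generating
program is recovered exactly.

`required_period()` inverts the forward model by bisection to half a cell
cycle and snaps to the smallest whole-cycle boundary attaining the target;
`required_founders()` uses exact linearity in the founder pool. Trade-off
targets quoted for an adult count (e.g. 10^9 neurons) are converted to
end-of-neurogenesis scale first.

## Progenitor dynamics

`build_stage_matrix()` assembles a stage-structured (Lefkovitch-style)
projection matrix over the lineages active in a program. The published
analysis names the ingredients (lineage-series sums after 100 cycles as
fecundities, proportional contributions as mortalities) but not the matrix
layout; the layout used here is `A[i, j] = p_i * f_j + (i == j) * p_j`
with per-cycle fecundity `f_j = L_j(100)/100` — newborn recruitment is
distributed over stages by the program weights and the program weight
doubles as the per-cycle survival of a stage. A single-lineage program
then yields a unit stable-stage vector, and zeroing the fecundity of the
proliferative lineages strictly lowers the dominant growth rate. The
eigenpair is computed densely and cross-checked against power iteration at
1e-10.

The ODE layer isolates one mother cell pool from the lineage context:
`a` asymmetrically dividing mothers (constant), `b` neurons, `c`
proliferative daughters, with direct-division likelihood `r`:

    a' = 0;   c' = (1 - r) a - k_m c;   b' = r a + 4 k_m c.

Each proliferative daughter performs one round of symmetric proliferation
followed by a self-consuming division, hence 4 neurons per matured
daughter; `k_m` (default 1 per cycle) is the maturation rate. The
right-hand sides are a reconstruction — the published equations are not
printed — but the limits fixed by the text hold exactly: at `r = 1`,
`c0 = 0` output is linear (`b = b0 + a0 t`), and at fixed `t` output is
maximal as the pool grows and `r` approaches 0 (indirect neurogenesis).
The closed-form solution is the implementation; `deSolve` integration
verifies it to 1e-8 in the tests.

## Founder-pool estimation

Ventricular surface is reconstructed from equally spaced coronal contour
lengths as trapezoid strips (`surface_from_sections()`, equal to the
shoelace polygon area), the apical end-foot as a regular hexagon with the
measured adherens-junction distance as its across-flats diameter
(`endfoot_area()`, `(sqrt(3)/2) d^2`), and founders as surface divided by
end-foot area. For species known only by ventricular volume, the
ventricle is approximated as a cylinder of height-to-diameter ratio 4.5
and the *lateral* surface only is used (the end caps are not ventricular
lining; switchable via `aspect` and the inverse
`cylinder_volume_from_surface()`), multiplied by the common founder
density of 4e5 cells/mm^2. Missing traits are imputed by ln-ln ordinary
least squares (`estimate_missing()`), with published coefficients usable
in place of a fit.

## Comparative statistics of the GI threshold

All allometries are fit on natural logarithms.

**Segmented scaling.** `segmented_regression()` fits 1–5 ordinary
least-squares segments and selects the count by AIC with `k = 3s`
parameters (slopes, intercepts, `s - 1` breakpoints, one residual
variance). Two breakpoint policies are provided because they answer
different questions. The default places breakpoints at the Jenks natural
breaks of the predictor: the x-distribution of grade-shifted allometries
is itself clustered, the boundary falls in the inter-regime gap, and the
AIC comparison across segment counts is then a fair nested comparison —
on generated two-regime data two segments are selected in >= 90% of
seeds and both slopes are recovered to ±0.01. The `"optimal"` policy
finds the exact RSS-minimising contiguous partition by dynamic
programming (validated against exhaustive enumeration); it is the right
tool when the segment count is fixed, but optimising breakpoints against
the residuals inflates the likelihood gain of additional segments (an
extreme-value effect that no parameter-count penalty of AIC form
repairs), so it is not the default for model selection.

**Slope contrast and threshold.** `slope_contrast()` performs the
two-sample slope t-test with pooled residual variance and
`df = n1 + n2 - 4`; it is validated against a permutation reference.
`threshold_estimate()` places the regime boundary at the midpoint between
the largest low-group and smallest high-group x (and y), with species
bootstrap uncertainty.

**Energy clustering.** `energy_dendrogram()` agglomerates scalar values
by the Székely–Rizzo e-distance
`(nm/(n+m)) (2 E|a-b| - E|a-a'| - E|b-b'|)`, merging the closest pair at
each step; the final (greatest-height) merge defines the top split. On
generated bimodal GI data the top split recovers the planted
below/above-1.5 partition with zero misassignments.

**Jenks natural breaks.** `jenks_breaks()` solves the optimal
contiguous partition (minimum within-class sum of squares) exactly by
dynamic programming, verified against exhaustive partition search.

**Brain weight per gestation day.** `brainweight_per_gestation()`
contrasts `ln(brain weight / gestation days)` across the GI 1.5 split
with a Welch t-test; the group fold-difference is the ratio of geometric
means `exp(mean_high - mean_low)` and is invariant to the units of brain
weight. With the published group means (−2.04 and 0.583) the fold is
`exp(2.623) ≈ 13.8`, the "about 14-fold" contrast.

## Phylogenetic trait layer

`fit_trait_model()` fits Brownian motion (rate, root state) by the
pruning algorithm — validated against a dense multivariate-normal
evaluation to 1e-8 — and the delta model by bounded optimisation of the
depth exponent on the transformed tree. `delta_transform()` normalises
node depths by the total depth, raises them to `delta` and rescales, so
total depth, topology and tips are preserved; `delta = 1` is the exact
identity. The delta fit is compared to Brownian by a likelihood-ratio
test on 1 df. `ancestral_states()` reconstructs internal nodes by GLS
prediction, including the root-mean uncertainty in the standard errors;
the root row's SE is the classical root SEM. `transition_directions()`
discretises the trait into bins, samples node states from their
reconstruction distributions, and counts bin decreases (high-to-low)
versus increases along every branch as minimal adjacent-bin paths.

Calibration, measured in the test suite at the sizes noted: on pure-birth
trees the ML delta recovers a planted 2.635 within ±0.5 of the mean over
50 replicates of 102 tips; the likelihood-ratio test keeps its nominal
size on Brownian data (>= 90% non-significant over replicates); and the
true root lies within ±2 SE in ≈ 95% of 200 replicates of 50 tips.

## Synthetic data

The generators define the study conditions for every stochastic test; all
randomness flows through the single integer `seed` argument and the same
seed reproduces outputs bit for bit.

* `gen_species_table()` draws neurogenic periods log-uniformly over the
  span of the reference table (9–115 days), cell-cycle lengths from the
  three observed values (18.5, 30, 45 h), founder pools log-uniformly
  over 2.5e4–3.2e7 cells, and produces "observed" adult counts by running
  the forward model itself under a known program with multiplicative
  log-normal noise (counts are positive and allometries ln-linear, so
  noise belongs on the log scale; default sd 0.05). At zero noise every
  downstream estimator is exact, which is how recovery tests are anchored.
* `gen_bimodal_gi()` plants two ln-linear GI-on-neuron-number regimes
  with the published slopes (0.072, 0.140), a gap at GI 1.5 and neuron
  numbers straddling 1e9 (group means ln 2e8 and ln 6e9, sds 0.6/0.7,
  truncated at the boundary — wide enough to span each regime, tight
  enough that the low regime stays above the GI = 1.0 floor, since
  clipping at the floor would create a third real regime), plus brain
  weights and gestation periods tuned so `ln(bw/gd)` has the published
  group means (−2.04, 0.583; between-species sd 0.3, a mid-range value
  for mammalian life-history scatter at fixed grade).
* `gen_tree_with_trait()` simulates pure-birth (Yule) ultrametric trees
  (the standard shape assumption in comparative-methods simulation;
  exposed via `birth`) and evolves traits by independent normal
  increments along branches, on the delta-transformed tree when
  requested.

What the generators do **not** emulate: phylogenetic autocorrelation in
the species parameter table, measurement error in founder pools or
periods, the GI = 1.0 floor (real lissencephalic species sit exactly at
the floor), body-mass covariation, and non-ultrametric (fossil) trees.
Passing recovery tests therefore demonstrate correctness of the
estimators under their own assumptions, not robustness to those
real-data features.

## Numerical choices and problem sizes

Tolerances: series/agent equality is exact (1e-12); eigen cross-checks
1e-10; pruning-vs-dense likelihood 1e-8; ODE closed-form vs numerical
1e-8; bisection to half a cell cycle. Degenerate inputs: zero founders or
zero neurogenic period predict zero neurons; `k = 0` makes every program
tie in inference (resolved by the documented tie-break); cluster and
partition routines refuse `n < 2`. The stochastic property tests use 50
replicates of 102 tips (delta recovery), 200 replicates of 50 tips (root
coverage), 100 seeds of 100 species (segment selection) — sizes chosen to
keep Monte-Carlo error well inside the asserted margins.
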