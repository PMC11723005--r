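---
title: "Growth, maturity and early selection in clonal progeny trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growth, maturity and early selection in clonal progeny trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popgrowth)
library(dplyr)
```

`popgrowth` analyses long-term clonal progeny trials of fast-growing
trees: annual DBH/height remeasurements of clones replicated over blocks,
in two populations formed by a direct and a reciprocal cross. This
vignette is the package's account of the methods: the quantities it
computes, the statistical model behind the simulator, the defaults and why
they are what they are, and the numerical edge cases.

## 1. From field measurements to stem traits

The raw record is one row per tree per year: clone, cross type (`DxM` or
`MxD`), block, tree, age (years since planting), DBH (cm at 1.3 m) and
total height (m). Three traits are derived per record:

* **Height–diameter ratio** `HDR = H / DBH`, deliberately on the mixed
  m/cm unit convention used in poplar trial reporting, so mature values
  fall around 0.6–0.8. HDR is a slenderness and stability index: lower
  values mean stockier stems that better resist wind and snow.
* **Basal area** `G = π·(DBH/100)²/4` in m².
* **Stem volume** `V = G · H · F` in m³, with the breast-height form
  factor `F = 0.44` reducing the basal-area cylinder to the tapering stem.
  `F` is a single fixed estimate — the package fits no allometric or taper
  models by design; every volume is the same deterministic function of the
  two field measurements.

Group means are always means of per-tree values. In particular a
population's mean volume is the mean of per-tree volumes, *not* the volume
formula applied to mean DBH and mean height: volume is convex in DBH, so
the two differ (applying the formula to a group's printed mean DBH/H
overshoots its printed mean volume), and only the mean-of-volumes order is
internally consistent. Missing tree-years (mortality) are dropped pairwise
within each analysis; nothing is imputed.

## 2. Increments and quantitative maturity

Per clone, from the mean-volume series `V(t)`:

* mean annual increment `MAI(t) = V(t)/t`,
* periodic annual increment `PAI(t) = V(t) − V(t−1)`, **indexed to the
  later age** of its one-year interval — the increment is observed at the
  later measurement, and this convention makes integer maturity ages line
  up with the annual schedule.

The quantitative maturity age (QMA) — the maximum-sustained-yield rotation
age — is the first age at which `PAI ≤ MAI` *after* at least one earlier
age with `PAI > MAI`. The prior-exceedance guard matters: a series that is
concave from its first measurement (PAI below MAI throughout) would
otherwise be assigned a spurious maturity at age 2; such clones are
flagged `immediate_decline` instead. A clone whose PAI is still above MAI
at the last age is `not_reached` — a real outcome for slow-growing clones,
reported as an explicit flag rather than an age.

Numerical details: exact ties (`PAI = MAI`) count as crossings at that
age; gaps in the age sequence leave PAI undefined on both sides (a
crossing is never interpolated across a missing year); alongside the
integer age the bracketing ages and a linearly interpolated real-valued
crossing are emitted for diagnostics. An optional centred 3-point moving
average over PAI (`smooth = TRUE`, off by default) suppresses year-to-year
measurement jitter for small clones; the default is off because annual
trial reports conventionally use raw increments.

## 3. Path analysis

To rank predictors of volume, each predictor's simple correlation with
volume is decomposed into a direct and an indirect part. With standardized
predictors, the direct path coefficient of trait *i* is the standardized
partial regression coefficient `DPC_i = B_i · S_i / S_y` (OLS fit of
volume on all predictors jointly), and the indirect path through mediator
*j* is `r_ij · DPC_j`. The reported IPC is the sum over mediators, which
makes the decomposition exact:

`DPC_i + IPC_i = Σ_j r_ij · DPC_j = r(i, V)`

— the normal equations themselves. The package asserts this identity to
1e-10 on every sample in its tests; it holds to machine precision.
Per-mediator terms are kept in the fit object (`ipc_matrix`) for
diagnosis.

Significance: the DPC carries the partial-regression t test of `B_i`; the
IPC carries the correlation test of `r(i, V)`, the total association it
completes. Trial reports star both columns without stating their test;
this is the conventional reading and is stated here so the output is
unambiguous. Stars are two-level throughout the package (`*` p < 0.05,
`**` p < 0.01); finer levels are collapsed into `**`.

Windowed analysis pools tree-by-year observations within age windows
(default `2-3, 4-6, 7-9, 10-12, 13-15, 16-18`) per cross type. Tree-level
observations are the unit — they maximize n within a window and match
pooled degrees of freedom; clone means would be the alternative when block
effects dominate, and every function takes whatever table it is given, so
passing `aggregate_means()` output switches the unit. A predictor set
that is exactly collinear in a window (possible when HDR is a deterministic
function of DBH and H in a degenerate sample) is rejected with an error
naming the set rather than silently dropped.

The per-age population comparison is a one-way ANOVA of tree-level values
between the two cross types. With two groups `F = t²` of the
pooled-variance t test (asserted to 1e-10 in tests). Zero within-group
variance with distinct means is reported as `F = Inf`, `p = 0`, flag
`degenerate` rather than an error: constant groups do occur in tiny or
simulated samples.

## 4. Age–age correlation and early selection efficiency

Early selection trades accuracy for time: the age–age correlation `R_p`
between a trait at early age `t_l` and at the mature reference age `t_e`
measures accuracy, and the efficiency score scales it by the years saved:

`ESE = R_p · t_e / t_l`

The default trait is DBH — the easiest trait to measure precisely and the
dominant direct path into volume — and the default mature reference age is
14, around late quantitative maturity. `ESE = R_p` when `t_l = t_e`, and
at fixed `R_p` the score falls as selection is delayed. The correlation
unit defaults to clone means per age (stable under tree-level mortality);
tree-level pairing by clone/block/tree id is available.

`optimal_window()` turns the table into a recommendation: the earliest
maximal run of consecutive ages where `R_p` is at least `rp_min` (default
0.50, the conventional lower edge of the "strong" band) and significant at
0.05. In joint mode (default) an age qualifies only if *every* cross type
qualifies — one population's moderate correlation disqualifies the age for
the programme. An optional `ese_min` adds an efficiency floor; it is off
by default because a defensible universal ESE threshold does not exist,
but it is how a "still early enough to be worth it" bound is expressed
(an ESE floor near 1.9 reproduces the narrow 4–5-year optimum of the
trial's published correlation profile, where the qualifying run otherwise
extends to age 13).

One genuine ambiguity is worth recording: trial write-ups sometimes
describe correlating against "the final year" while their efficiency
arithmetic uses the late-maturity age. The package defaults `late_age` to
14 — the value consistent with published ESE worked examples
(0.88 × 14/7 = 1.76) — and exposes it as an argument rather than deciding
for the user.

## 5. Survival filtering, selection and stability

Clones enter the trial only if nursery cutting survival meets the
threshold (default 60 %). The comparison is **inclusive** — a clone at
exactly 60 % is retained — because the census convention this mirrors
keeps the boundary clone. The survival table is keyed by clone × cross
type; an id listed under both cross types is legal but surfaced in a
validation attribute rather than silently resolved.

Selection ranks candidate clones by clone-mean volume at the reference age
(default: last measured age) and keeps the top `floor(rate · n)`, minimum
one — at the trial's 25 % rate, 17 candidates yield 4 selections (ceiling
would give 5). Ties break deterministically: higher mean DBH, then
lexicographic clone id. Selected clones are flagged per trait against
their own population mean; for HDR the flag inverts, since *below* the
mean is the favourable, stockier side.

Stability is the volume coefficient of variation `CV = 100·s/x̄` (sample
SD) over tree-level volumes at the reference age: population CV measures
how unevenly a cross's members grow, clone CV measures ramet uniformity.
CVs are reported unrounded and conventionally displayed at whole percent.

## 6. The trial simulator

Because per-tree trial data are rarely deposited, the package ships a
generator with the statistical structure the analyses assume, and the test
suite runs the entire pipeline against it.

**Model.** Both DBH and height follow three-parameter logistic curves in
age, `x(t) = K / (1 + exp(−r (t − t0)))`; volume is *not* simulated
directly but emerges through the form-factor equation, which guarantees
the sigmoid volume trajectory and a PAI/MAI crossing. Hierarchy of
variation:

* **Cross-type means** (frozen defaults): DxM DBH `K = 36 cm, r = 0.42,
  t0 = 7 yr`, height `K = 25.5 m, r = 0.45, t0 = 5 yr`; MxD DBH
  `K = 32.5, r = 0.40, t0 = 7.5`, height `K = 24.5, r = 0.45, t0 = 5.3`.
  These were calibrated once against the published scale of the poplar
  trial the package models — mature DBH near 35/32 cm and height near
  25/24 m, HDR declining monotonically from ~1.3–1.4 to 0.71/0.76 with
  the reciprocal cross higher early, noise-free maturity inside the
  12–16-year band, peak PAI near age 10 — and then frozen; they are the
  study conditions, not tuning knobs.
* **Clone effects**, one draw per clone: multiplicative on each asymptote
  (relative SD 0.10) and a single additive shift of both inflection years
  (SD 0.8 yr) — a clone is early or late as a whole. These stable effects
  are what make late-age clone rankings consistent, and hence age–age
  correlations rise with age.
* **Tree effects**: multiplicative asymptote effect (relative SD 0.04),
  stable ramet quality.
* **Measurement noise**: additive Gaussian per tree-year (SD 0.6 cm DBH,
  0.4 m height), truncated just above zero.
* **Mortality**: Bernoulli per tree-year (p = 0.02), truncating the
  tree's series at death — the attrition pattern of a real trial.

All draws come from a single root generator in a documented stream order
(clone effects in clone order, then per-tree effects, death year and noise
clone by clone), so one integer seed reproduces the whole trial.

**The analytic maturity oracle.** For noise-free curves the maturity age
is computable independently of the pipeline: a dense grid (0.01 yr) plus
bisection finds where `V(t) − V(t−1)` falls back to `V(t)/t`. The
increment is indexed to the later age of its interval, matching the
discrete schedule, so integer maturity ages from noise-free simulated data
land within one year of the oracle — a property the tests assert for all
17 clones. Under default measurement noise the agreement is necessarily
looser (year-to-year jitter in PAI moves the detected crossing by a year
or two for a minority of clones); the regression test pins the frozen
behaviour at ≥ 80 % of clones within a year at the reference seed.

**What the generator does not emulate.** No site, climate or competition
effects; no block effects (blocks exist structurally but add no
variance); no genotype-by-year interaction; noise independent across
years, whereas real remeasurement errors correlate within a tree;
mortality independent of vigour. Passing tests therefore demonstrate that
the pipeline recovers the structure this model encodes — not that any
biological claim about a particular trial is reproduced.

## 7. Problem sizes and reproducibility

The shipped tests and the acceptance script use the trial-scale design
throughout: 17 clones × 8 trees × 17 annual measurements (≈ 1 900–2 300
rows after mortality), 20 replicate simulations for parameter-recovery
checks, and 100 random samples for the path-identity property — sizes at
which the full suite runs in well under a minute. `scripts/acceptance.R`
reruns the pipeline end to end from a single `--seed` and writes every
headline quantity as JSON; the published summary tables it uses as fixed
inputs (survival census, age–age correlations, mature trait means) are
plain CSVs under `inst/extdata/`.

## 8. Known limitations

* The fixed form factor makes volume exact in DBH and height; real stem
  form varies with age and site, so absolute volumes carry that bias.
* Integer-age QMA reporting quantizes the crossing; the interpolated
  crossing is emitted but the headline value follows the annual schedule.
* Path analysis is a single-layer decomposition on observed traits; it is
  not a causal structural model, and with HDR a deterministic ratio of
  the other two predictors its paths describe association geometry only.
* The IPC convention (sum of `r_ij · DPC_j` over mediators) is stated
  explicitly because published tables are not always recoverable to a
  unique convention; comparisons across reports should check conventions
  first.
* Two-level significance stars understate very strong evidence
  (p < 0.001 prints as `**`).
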