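---
title: "Chill-unit models and coexpression hub screening for bud dormancy release"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chill-unit models and coexpression hub screening for bud dormancy release}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(dormabreak)
```

## The problem

Rhizome buds of species such as *Polygonatum kingianum* enter endodormancy
shortly after forming and need a sustained period of chilling before they
will sprout under warm conditions. Classical chill models (chilling hours,
Utah and its relatives) were built for fruit trees and transfer poorly, so
the chilling requirement has to be characterised per species: how efficient
is each temperature at releasing dormancy, how much accumulated chilling
does a bud need, and which genes track the transition from endodormant to
ecodormant to nondormant buds.

`dormabreak` implements that workflow as a tested pipeline with three
layers:

1. **Chill units from sprouting curves.** Replicated time-courses of
   cumulative sprouting percentage (recorded daily under warm conditions
   after chilling at temperature $T$ for $d$ days) are reduced to a
   per-temperature chill unit, a quadratic model is fitted, and chilling
   accumulation is integrated over arbitrary temperature schedules.
2. **Accumulation-to-sprouting (CAS) stage models.** Quadratic maps from
   chilling accumulation to the sprouting percentage reached by a fixed
   warming day, invertible for "how much chilling buys 90% sprouting".
3. **Weighted coexpression network.** A from-scratch implementation of the
   weighted-correlation workflow (soft threshold, adjacency, topological
   overlap, modules, eigengenes, module--trait correlation, gene
   significance/module membership, degree-based hub screen) applied to an
   FPKM matrix of dormancy-state samples scored by sprouting percentage.

Synthetic-data generators with known ground truth sit beside the analysis
code so every stage can be exercised end to end and its recovery behaviour
quantified.

## Chill units and the quadratic model

For each treatment $(T, d)$ the replicate-mean cumulative curve is reduced
to its **rising-phase slope**: the ordinary least-squares slope of
sprouting percentage on warming day, restricted to the window from the
first day with a positive value to the first day reaching the curve's
maximum. The window rule needs two conventions, both handled explicitly:
an all-zero curve gets slope 0 with a `no_emergence` flag, and a
single-day window is extended to the last pre-emergence day (or an implied
0% at day 0) so a slope is always defined.

The chill unit of temperature $T$ is a slope ratio,

$$\mathrm{CU}(T) = \frac{\overline{s}(T)}{\overline{s}(T_{\mathrm{ref}})},$$

where $\overline{s}(T)$ is the unweighted mean slope over chilling
durations and $T_{\mathrm{ref}} = 0\,^\circ\mathrm{C}$ by default, so
$\mathrm{CU}(0) = 1$ exactly and the table is invariant to uniform count
rescaling. Flat-curve slopes enter the mean as 0 (a temperature at which
only long treatments produce sprouting is genuinely less efficient);
temperatures at which *no* curve leaves zero are flagged and excluded from
model fitting, since they carry no slope information.

The model itself is an unweighted least-squares quadratic
$Y = aX^2 + bX + c$ ($X$ = chilling temperature in deg C, $Y$ = chill
unit), required to be concave ($a < 0$). Its derived constants are closed
forms: the optimum temperature $-b/(2a)$, the maximum chill unit
$c - b^2/(4a)$, and the upper limit of chilling effectiveness, the larger
root of the quadratic:

```{r}
m <- chill_unit_model(a = -0.0154, b = 0.0916, c = 0.9926)
m
```

Evaluation clamps to zero outside $[0, t_{\mathrm{upper}}]$: there is no
anti-chilling term, warmth above the upper limit contributes nothing, and
sub-zero temperatures (which damage buds rather than chill them
efficiently) contribute nothing and raise a warning.

**Chilling accumulation** takes the hourly time base literally: one hour at
temperature $T$ contributes $\mathrm{CU}(T)$, so a schedule of segments
$(h_i, T_i)$ accumulates $\mathrm{Ca} = \sum_i h_i\,\mathrm{CU}(T_i)$ in CU
hours, with 24 h per day for constant-temperature treatments. The segment
formula is exactly additive and invariant to subdivision; the test suite
checks it against hour-by-hour brute-force summation. `ramp_schedule()`
builds the verification-style program (daily 1 deg C increments, endpoints
included, then a hold); a ramp whose increments are each held longer can be
assembled directly with `temperature_schedule()`.

```{r}
chilling_accumulation(m, constant_schedule(2, 71))  # best field treatment
```

## CAS stage models

`stage_observations()` pairs each treatment's accumulation
$\mathrm{Ca} = \mathrm{CU}(T) \times 24 \times d$ with the replicate-mean
sprouting percentage read at a stage day (37, 40, 44 and 50 by default);
cumulative curves are step functions, so a stage day between recorded days
reads the latest earlier value. Treatments with zero chill unit deliver no
chilling and are excluded. The stage model is a least-squares quadratic
$p(\mathrm{Ca}) = \alpha\,\mathrm{Ca}^2 + \beta\,\mathrm{Ca} + \gamma$,
with predictions clamped to $[0, 100]$. The quadratic form is the minimal
class supporting the reported interior optimum (supra-optimal chilling
reduces sprouting); fits with $\alpha \ge 0$ are stored with a "no
optimum" flag rather than rejected.

Two inverses matter agronomically. `optimum_ca()` is the vertex
$-\beta/(2\alpha)$. `required_ca()` returns the *lower* crossing of a
target percentage — the smallest sufficient chilling — solved analytically
from the quadratic roots, with the vertex added as a candidate so exact
tangency (target equal to the model maximum) resolves cleanly.

`verify_predictions()` frames verification the way the field plots it:
$R^2$ (squared Pearson correlation), the observed-on-predicted regression
slope and intercept (a perfect model sits on $Y = X$), and the mean signed
bias.

## The sprouting-curve generator

`simulate_sprouting()` draws experiments from a known chill-unit model so
the whole chilling pipeline can be tested against planted truth. For a
tray at $(T, d)$ with $\mathrm{Ca} = \mathrm{CU}_{\mathrm{true}}(T) \cdot
24 \cdot d$:

* each of the `n_buds` buds sprouts independently with probability
  $\mathrm{plateau}(\mathrm{Ca})/100$ (binomial tray noise — the only
  replicate-level noise source, an explicit assumption since replicate
  variances are not otherwise constrained);
* a sprouting bud emerges on a day drawn from a logistic distribution with
  location $\mathrm{delay}(\mathrm{Ca})$ and scale
  $1/\mathrm{rate}(\mathrm{Ca})$, rounded up to a whole day.

The three response functions encode the qualitative behaviour of real
chilling-response curves:

| function | form | default | encodes |
|---|---|---|---|
| plateau (%) | $100(1 - e^{-\mathrm{Ca}/260})$, linear decline $0.01\,\%/\mathrm{Ca}$ beyond 1900 Ca | saturates by ~1200 Ca | final sprouting rises with chilling; supra-optimal chilling is mildly harmful (unimodal) |
| delay (days) | $14 + 40\,e^{-\mathrm{Ca}/500}$ | 15--54 days | poorly chilled trays emerge late |
| rate (day$^{-1}$) | $0.05 + 10^{-4}\,\mathrm{Ca}$ | 0.05--0.27 | well-chilled trays emerge fast and uniformly |

The Ca-dependent steepness is load-bearing: the chill-unit estimator is
built on curve *slopes*, and with a fixed emergence scale the slope would
carry chilling information only through the plateau, which saturates over
most of the design — the estimator the package implements would be testing
noise. Making emergence uniformity improve with chilling (which is also
what real curves show: slopes visibly fall as chilling temperature rises
toward the ineffective range) puts the chilling signal where the estimator
looks for it.

Defaults mirror the field design: temperatures $-2$ to $14\,^\circ$C
(including one damaging and two ineffective temperatures, which produce
flat curves), twelve durations from 5 to 81 days, 3 replicates of 20 buds,
70 warming days. All randomness flows through one seeded generator;
identical seeds give identical CSV output.

What the generator does **not** model: temperature-dependent emergence
delay beyond its dependence on Ca (real 10 deg C treatments emerge later
than equal-Ca 0 deg C treatments), bud-to-bud heterogeneity beyond the
binomial, damage dynamics at $-2\,^\circ$C (those trays are simply flat),
and alternating-temperature effects. Passing recovery tests therefore show
the estimators work when their modelling assumptions hold at field-design
sample sizes — not that the fitted field constants are themselves correct.

## The expression generator

`simulate_expression()` emulates the structure of the study matrix: 9
samples (endo-, eco-, nondormant, in triplicate) scored by sprouting
percentage, a block-correlated gene set, and a few modules strongly linked
to the trait. Each module $m$ has a latent per-sample profile constructed
to have an *exact* sample correlation $r_m$ with the trait (for $r_m = 0$,
exactly orthogonal); module genes are
$\mathrm{baseline} + \mathrm{loading} \times \mathrm{latent} +
\mathcal{N}(0, \sigma)$ on the log scale, exponentiated to FPKM.

Three design choices were fixed by an identifiability analysis at $n = 9$
samples, where empirical correlations fluctuate with a Fisher-$z$ standard
deviation of $1/\sqrt{6} \approx 0.41$:

* **Trait-linked modules share an anti-aligned residual direction.** Two
  latents both correlated at $|r| = 0.95$ with one trait can never be less
  correlated with each other than $2r^2 - 1 = 0.805$ in magnitude; sharing
  the orthogonal component (with sign chosen to cancel) attains that lower
  bound, keeping the two trait modules as distinguishable as mathematics
  allows in an unsigned network.
* **Module cores are tight** (loadings 0.6--0.78, log-noise 0.22,
  within-module correlations ~0.85--0.9), as expected for genes
  pre-filtered to be differentially expressed across dormancy states.
  Weaker cores are not recoverable as coherent modules at $n = 9$ under a
  high soft power.
* **Engineered hubs are unambiguous**: loading 1, log-noise 0.02, and
  baseline log-FPKM floored at 3. The floor matters because near-zero FPKM
  is compressed by the `log1p` transform used downstream; a soft power of
  26 amplifies the resulting correlation deficit enough to demote a
  low-expressed "hub" — planted truth must not be ambiguous.

## The network stage

All correlation work runs on `log1p(FPKM)` (FPKM spans decades; raw-scale
Pearson correlation is dominated by outliers; a `transform = "none"`
switch is provided). Zero-variance genes are flagged on construction,
retained in the matrix, and excluded from correlation operations with a
warning.

The network is unsigned: $a_{ij} = |\mathrm{cor}(x_i, x_j)|^\beta$ with
$a_{ii} = 0$, and the topological overlap

$$\mathrm{TOM}_{ij} = \frac{\sum_u a_{iu}a_{uj} + a_{ij}}
{\min(k_i, k_j) + 1 - a_{ij}}, \qquad \mathrm{TOM}_{ii} = 1.$$

`pick_soft_threshold()` reports, per candidate power, the signed
scale-free fit $R^2$ (regression of $\log_{10}$ frequency on $\log_{10}$
binned connectivity over 10 bins; rising slopes are penalised by sign) and
the mean connectivity, choosing the smallest power reaching $R^2 \ge
0.85$, else the argmax. A caution that the package's own tests act on: at
$n = 9$ this rule tends to select small powers (5--6) because even chance
correlations ($|r| \sim 0.6$ happens freely at 9 samples) produce a
passable degree distribution — yet those chance edges glue background
genes onto modules. The planted-recovery tests therefore run the network
at $\beta = 26$, the scale appropriate for a 9-sample unsigned design; the
pipeline accepts an explicit `beta` override and records it in the
provenance file.

Modules come from average-linkage clustering of $1 - \mathrm{TOM}$ with a
**static** cut (default height 0.9, minimum size 30, smaller clusters
labelled `"unassigned"`). A static cut is used deliberately instead of the
dynamic tree-cut heuristic: it is simple enough to test exactly and keeps
the reimplementation honest, at the documented cost of not reproducing
partitions that depend on the dynamic algorithm's internals. Genes are
processed in lexicographic id order, so the partition is invariant to
input order; modules are named from the conventional colour sequence
(turquoise, blue, brown, ...) in decreasing size order with ties broken by
smallest member id.

Eigengenes are first principal components of the module's standardized
log-expression (unit norm, sign-oriented to non-negative mean correlation
with member genes). Module--trait correlation, gene significance
$\mathrm{GS}_i = \mathrm{cor}(x_i, \mathrm{trait})$ and module membership
$\mathrm{MM}_i = \mathrm{cor}(x_i, \mathrm{ME}_{m(i)})$ are plain Pearson
correlations with closed-form $t$-test p-values ($t = r\sqrt{n-2}/
\sqrt{1-r^2}$, 7 df at nine samples); magnitudes are stored alongside
signed values because significance thresholds apply to magnitudes.

## The hub screen

Within each significant module (module--trait $|r| > 0.9$, strictly), the
screen is: build the edge list at the module's weight threshold (strict
$>$, on TOM by default — a config switch allows raw adjacency), count
degrees, cluster degrees with seeded 1-D $k$-means (default $k = 3$,
10 restarts), keep the *first cluster* (highest mean degree), and require
$|\mathrm{GS}| \ge$ `gs_min` and $|\mathrm{MM}| \ge$ `mm_min`
(inclusive). The report records each criterion per gene so stricter or
looser readings of the screen can be recovered after the fact. The hub set
is monotone non-increasing in each threshold.

Package defaults keep the field thresholds (`gs_min = 0.95`,
`mm_min = 0.98`). The *recovery tests* use thresholds matched to their own
planted design instead (`gs_min = 0.85`, `mm_min = 0.985`): with a
module--trait correlation planted at $r = 0.95$, even a noise-free module
gene has true $|\mathrm{GS}| \le 0.95$, so demanding 0.95 would make
recovery a coin flip on sampling noise rather than a property of the
screen. Edge thresholds in the tests are set per module at the 90th
percentile of within-module TOM weight — fixed absolute thresholds do not
transfer across modules whose weight scales differ, which is also why the
field workflow used a different threshold for each module.

## Numerical conventions and degenerate inputs

* Percentages are computed as exact ratios ($100 \times
  \mathrm{sprouted}/n$) before any rounding; cumulative counts that
  decrease or exceed the tray size are validation *errors*, never
  repaired.
* `fit_cu_model()` and `fit_cas()` refuse under-determined designs (< 3
  distinct abscissae) and report concavity violations ("no interior
  optimum") rather than returning a vertex extrapolated from a convex fit.
* Serialized models store coefficients *and* derived constants; readers
  recompute the latter and refuse files where the two disagree (relative
  tolerance $10^{-6}$).
* `hclust` average-linkage heights are forced monotone (`cummax`) before
  cutting; floating-point ties can otherwise leave heights microscopically
  out of order.
* 1-D $k$-means reduces $k$ with a warning when there are fewer distinct
  degree values than clusters; with one distinct value all genes are
  returned.
* The correlation p-value uses the closed form rather than resampling;
  at $r = \pm 1$ the variance term is floored at machine epsilon.

## Problem sizes used by the test suite

The recovery tests run at the scale of the designs they mirror: the
chilling pipeline at 9 temperatures $\times$ 12 durations $\times$ 3
replicates $\times$ 20 buds over 20 seeds (optimum-temperature recovery)
and 10 seeds (held-out stage-model verification, with a 7-duration held-out
design); the network stage at 1000 genes $\times$ 9 samples over 20 seeds
for module recovery and module--trait significance and 10 seeds for the
hub screen; oracle equivalences (brute-force TOM, exhaustive 1-D
$k$-means, direct correlation recomputation) at 12--120 genes. These sizes
are the package's chosen balance between statistical resolution and a test
suite that runs in a few minutes.

## Known limitations

* The chill-unit slope window is a convention; the field protocol does not
  pin down how "the average slope of the chilling-response curves" treats
  partial emergence, and different windows shift chill units slightly
  (ratios are more stable than raw slopes).
* Verification against ramped schedules assumes Ca is schedule-additive;
  alternating-temperature synergies (observed in several species, and a
  plausible reason verification observations run slightly above
  predictions) are outside the model class.
* The CAS quadratic extrapolates beyond the largest deliverable
  accumulation of a constant-temperature design; optima quoted from its
  vertex can exceed the observed Ca range and should be read as
  model-internal quantities.
* The static tree cut will not reproduce partitions produced by
  dynamic-cut implementations on real data; the module boundary behaviour
  differs exactly where the dendrogram is ambiguous.
* At 9 samples, gene-level statistics (GS, MM, degree) have large sampling
  variance; the hub screen's output should be read as a candidate list,
  not a verdict — which is also how the field uses it.
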