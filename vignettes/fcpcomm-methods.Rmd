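---
title: "Modelling community composition from functional genes: methods and design"
author: "fcpcomm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling community composition from functional genes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcpcomm)
```

## The model

`fcpcomm` models a microbial community of `num` taxa with replicator
dynamics under variable population size. Writing `x` for the vector of
relative abundances (on the simplex) and `N` for total population size,

$$
\dot x_i = N^{c-1}\left(f_i x_i^c - x_i \sum_j f_j x_j^c\right),
\qquad
\dot N = N^c \sum_j f_j x_j^c - dN ,
$$

with fitness

$$
f = A\,x + h, \qquad A = L - S .
$$

`S` is the matrix of pairwise Pearson correlations between the species'
COG hit-count vectors (their functional-gene usage), `L` is the all-ones
matrix, so `A` rewards functional *dissimilarity*: two taxa that use
different gene repertoires compete less and benefit more from coexisting,
while environmental filtering — the tendency of a shared environment to
select functionally similar organisms — enters through the offsets
`h = B e`, a sparse linear map of measured environmental factors learned by
Lasso regression.

The growth index `c` makes growth sub-exponential for `0 < c < 1`,
reflecting the slow catabolism of cells in oligotrophic or extreme
environments; `c = 1` recovers the classical replicator equation and is
admitted by the classes for reference computations. Two structural facts
follow directly from the equations and shape the whole package:

* the prefactor `N^{c-1}` only rescales time in the composition equation,
  so the *composition* trajectory is independent of `N0` and of the death
  rate `d` (both affect `N` alone). The package's insensitivity checks
  confirm this numerically rather than assuming it.
* at `c < 1` the map `x ↦ f(x)` pins the interior rest point through
  `x_i \propto f_i^{1/(1-c)}` (species with `f_i ≤ 0` go extinct). Equal
  fitness therefore does **not** freeze an arbitrary composition — it
  drives the community to the uniform one. Only in the classical `c = 1`
  limit is every composition neutral under equal fitness.

## Functional similarity: double-zero exclusion

Each species pair is correlated only over the COGs present in at least one
of the two genomes. A gene family observed in neither genome carries no
information about the pair's functional relationship, and shared absences
are conventionally excluded in community ecology for exactly this reason.
Two useful invariants follow: padding a table with all-zero COG columns
cannot change `S`, and an in-silico knockout can only alter the rows and
columns of species that actually carry the knocked-out gene. Pairs whose
masked count vectors have zero variance get a neutral similarity of 0 with
a warning. Correlation uses raw counts by default (Pearson is location and
scale invariant, so genome-size effects largely cancel); per-genome
proportions are available as `normalize = "proportion"` for sensitivity
analysis.

COGs with identical hit-number vectors are indistinguishable to `S`, so
screening and reporting work in units of unique profiles
(`dedupeProfiles()`), with results propagated to member COGs.

## Steady states: fixed point first, integration as referee

Predictions are compositional steady states. Setting `ẋ = 0` gives the
interior equilibrium condition `x_i = f_i^{p}/\sum_j f_j^{p}` with
`p = 1/(1-c)`, which `steadyState()` solves by a damped fixed-point
iteration (damping 0.5, tolerance 1e-13, negative fitness clipped to zero
so extinct species stay extinct). This is orders of magnitude faster than
time integration and agrees with `deSolve::lsoda` on random models to
solver tolerance; the ODE route (`integrateFCP()`, adaptive, stiff-capable,
convergence declared when `max |ẋ|` stays below `tol = 1e-8` across a
reporting interval) remains the implementation of record for trajectories,
the fallback when the iteration fails, and the only route at `c = 1`.
Powers `x^c` use the continuous extension `0^c = 0`, with negative
round-off clipped before exponentiation.

## Fitting: gauge freedom and how the package resolves it

A single observed composition does not identify `(h, c)`. Since only the
direction of `f` matters at steady state, any positive rescaling of `f` —
and in fact any `c` — can reproduce a given composition exactly via
`h = \varphi\, x^{1-c} - A x`. The package handles this explicitly instead
of hoping an optimizer lands somewhere consistent:

* **Canonical gauge.** Reported offsets are normalised so that
  `\sum_i f_i^{1/(1-c)} = 1`, under which the exact-fit fitness is simply
  `f = x^{1-c}` and `canonicalOffsets()` has a closed form. `fitSample()`
  runs the multi-start box-constrained quasi-Newton search the procedure
  calls for (default 100 random starts, `|h_i| ≤ 10`, `c ∈ [0.05, 0.95]`)
  plus one deterministic start at the canonical solution, and canonicalises
  every result, so fits are comparable across starts and samples. Multi-
  start consistency (the fraction of converged starts agreeing with the
  modal composition) is reported as a robustness diagnostic.
* **Scale profiling.** When the environment map is learned, a free positive
  scale per training sample is profiled out of the regression by
  alternating least squares: the canonical fitness of sample `s` equals an
  unknown `\psi_s` times `A x_s + B z_s`. The `A x` term anchors the
  overall scale, so `B` is identified in the gauge that prediction needs.
* **Consensus growth index.** Per-sample fitted `c` values are arbitrary on
  noiseless data, so the consensus `c` used at prediction time is chosen by
  minimising the cross-sample profiling residual over a grid
  (0.15–0.90 in steps of 0.05), normalised by the response's own variance
  (the scale of `x^{1-c}` shrinks as `c → 1`, so raw residuals are not
  comparable across the grid). On synthetic data this recovers the
  generating `c` to within one or two grid steps; with few training samples
  it has a mild upward bias, which is harmless for composition prediction
  because training and inversion share the gauge. `growthIndex = "median"`
  (median of per-sample fits) and fixed numeric values remain available.

## The environment map

`fitEnvMap()` regresses canonical offsets on standardised factors
(training means and standard deviations; missing cells imputed at the
training mean, i.e. zero after standardisation). Three further choices
matter:

* **Group sparsity across species.** Which factors matter is a property of
  the shared environment, not of each taxon separately, so the default
  penalised fit is a multi-response (group) Lasso: a factor is selected or
  dropped jointly for all species. With 13 correlated factors and of the
  order of 15 samples, per-species selection is unstable; the grouped fit
  recovers the active support far more reliably.
* **Censoring of absent species.** A species absent from a sample only
  bounds its fitness above by zero. Its entry is treated as censored: in
  each alternating step the working response is `min(fitted, 0)` for
  absent entries (an EM-style update), rather than being regressed toward
  an arbitrary value or discarded.
* **Penalty.** `penalty = "cv"` selects the weight by k-fold
  cross-validation (`k = min(5, n)` with a seeded fold assignment);
  `penalty = 0` reduces exactly to (weighted) ordinary least squares, which
  the tests verify against the normal equations; very large penalties give
  an all-zero `B` with per-species intercepts.

Prediction applies `h = B z(e) + intercept` with training-set
standardisation constants and solves the dynamics from `x0` (default: the
mean training composition) at the consensus `c`. `envInfluence()`
aggregates `B` into percentage influences per factor (sum of absolute
standardised coefficients over species, normalised to 100).

## The knockout screen for structure-shaping genes

A community-structure-shaping (CSS) gene is one whose in-silico loss moves
the predicted composition more than small random disturbances do:

1. **Null.** `perturbationNull()` multiplies every off-diagonal entry of
   `A` by `1 + ε`, `ε ~ N(0, noiseSd²)` symmetrised (default
   `noiseSd = 0.01`, "small" relative to interaction entries of order 1;
   disturbing `A` matches the mechanism by which gene loss acts), re-solves
   the steady state, and records Bray–Curtis similarity to the baseline,
   10,000 times by default. The significance threshold is the one-sided
   Student-t lower bound `mean(BC) − t_{1−α, n−1}·sd(BC)` (default
   `α = 0.05`). Raising `α` raises the threshold and can only enlarge the
   CSS set; the tests assert this monotonicity. If the null collapses to
   zero spread (e.g. vanishing `noiseSd`), the t test has no resolution:
   the null is flagged degenerate, the threshold is reported as 1, and no
   knockout is called.
2. **Screen.** For every unique profile group and each of the 50 retained
   best-objective parameter groups of the sample, the group's COG columns
   are zeroed, `A` is rebuilt, and the steady state is compared to that
   parameter group's own baseline. The fitted `h` and `c` are retained —
   losing a gene changes the functional similarity structure, not the
   environment. A group is CSS under a parameter group when its knockout
   similarity falls below the threshold; its CSS probability is the
   fraction of parameter groups flagging it. A knockout that leaves `A`
   bit-identical (e.g. an all-zero COG) is never CSS.
3. **Catalog.** `screenAllSamples()` repeats this per sample and assembles
   the union of per-sample calls: a gene can only shape the structure of
   communities in which its carriers are present, so per-sample screens are
   complementary. Per-sample call rates are reported for calibration
   checks.

Downstream, `enrichmentTest()` runs a two-sided Fisher's exact test per
functional category (a COG with several categories counts once in each),
reporting raw and Benjamini–Hochberg-adjusted p values, and
`overlapPermutationTest()` compares a gene set against an external one
(e.g. essential genes) with an add-one-smoothed empirical p value over
10,000 same-size random draws.

## The synthetic world

The generator supplies a fully known ground truth at the scale of the
motivating study design (9 species, a few hundred COGs, 17 samples,
13 factors):

* **Profiles.** Background hit counts are negative binomial with per-COG
  base rates from Gamma(2, 2) — most COGs at 0–5 copies, as in real
  genomes — and presence patterns shared within taxon blocks, giving allied
  species positively correlated count vectors and hence realistic `S`
  structure. Planted structure-shaping COGs emulate high-copy mobile
  elements: each sits in one species pair at Poisson(60) + 25 copies, so it
  dominates that pair's covariance and its removal measurably shifts `S`.
  A few columns are duplicated to exercise deduplication.
* **Environment and truth.** Factors are correlated Gaussians in
  natural-looking units with the first two tightly coupled (the
  pH–temperature cluster of acid-drainage sites); the true `B` has exactly
  `nActive` nonzero columns with the first active factor dominant; the true
  `c` is uniform on (0.3, 0.8); effect size 0.3 on standardised factors
  keeps fitness mostly positive while producing meaningful compositional
  variation (occasional extinctions included — deliberately, since real
  samples have them).
* **Abundances.** Steady states of the true model, optionally jittered by
  logistic-normal observation noise (Gaussian on log abundances, then
  renormalised — the noise respects the simplex).

What passing recovery tests on this world shows: that the estimation
pipeline inverts the model it claims to invert, at the study's scale, under
exact model specification plus controllable noise. What it cannot show:
robustness to misspecified interactions (real communities are not fully
described by `1 − S`), unmeasured environmental drivers, compositional
measurement bias, or taxonomic aggregation effects — on real data these
will dominate the error budget.

## Numerical and degenerate-input choices

* Fixed-point iteration: damping 0.5, tolerance 1e-13, 20,000 iteration
  cap, ODE fallback; ODE chunks of 25 time units with dense reporting and
  `lsoda` tolerances 1e-10/1e-12.
* Ties in deduplication are broken lexicographically by profile vector;
  screening output is sorted by probability, ties by group id, so output is
  byte-stable.
* All-zero species rows are rejected at load; all-zero COG columns are
  legal and inert. Abundance rows are renormalised on load with a message.
* Every stochastic step draws its seed from the master seed via a labelled
  LCG fold (`deriveSeed()`), so any sub-computation is reproducible in
  isolation; results and manifests are written with fixed float formats.
* Problem sizes in the shipped tests and acceptance script (a 9 × 300
  world, 5 held-out samples, 1,000-draw nulls, screens over 5 samples, 50
  parameter groups) were chosen as the smallest sizes at which the
  recovery behaviour is stable; the screening default of 10,000 null draws
  remains the config default.

## Known limitations

* Per-sample `(h, c)` are reported in the canonical gauge; they are
  comparable to each other but are not the "true" fitness scale, which no
  compositional observation can supply.
* The consensus-`c` profiling criterion is biased upward for very small
  training sets; predictions are insensitive, but `c` itself should not be
  over-interpreted.
* The screen's null disturbs `A` multiplicatively; alternative nulls
  (disturbing `h` or `x0`) would answer slightly different questions and
  are not implemented.
* With `num` above a few dozen taxa the per-sample multi-start fit
  dominates runtime; the defaults target low-complexity communities.
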