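---
title: "Surrogate-assisted optimization of culture media: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surrogate-assisted optimization of culture media: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mediaopt)
```

## The problem and the model

Micropropagation and related bioprocess responses depend non-linearly
on many interacting factors — growth-regulator concentrations, carbon
source, basal salts, environment — and every evaluation of a candidate
medium costs weeks of laboratory work. `mediaopt` treats the measured
responses as unknown functions of the formulation, fits fast
regression surrogates to existing experimental data, and lets
evolutionary algorithms search the formulation space against those
surrogates. The output is a ranked set of candidate media to validate,
not a claim of a proven optimum: the surrogate's error bounds the
quality of everything downstream, which is why model selection is
scored strictly on a held-out test set.

## Experimental designs

Five generators cover the usual regimes. Full factorials enumerate a
declared level grid. The central composite design combines the
$2^k$ cube, $2k$ axial points and $n_0 = \max(4, 2k)$ center points;
the default axial distance $\alpha = 0.8$ deliberately keeps axial
points *inside* the cube in coded units so no run requests a negative
concentration — the classic rotatable $\alpha = \sqrt[4]{2^k}$ would
leave the feasible range. Box-Behnken designs place points on edge
midpoints (never more than two factors at an extreme) for systems
where simultaneous extremes kill cultures; they need $k \ge 3$ because
with two factors the edge-midpoint set collapses into an ordinary
two-factor grid. The Latin hypercube divides each range into $n$
equal-width intervals with exactly one draw per interval ("equal
probability" equals equal width under the uniform ranges used here;
non-uniform priors are out of scope). The random design falls back to
the full grid at $G \le 50$ combinations and otherwise samples
$n = \mathrm{clamp}(0.30\,G, 20, 100)$ runs; the $2^k$ corner
combinations are forced in only while $2^k \le n/2$ (in high dimension
corners would otherwise flood the budget) plus one center combination
(lower-middle level for even level counts) so curvature remains
detectable. Replicate cleanup keeps the first five rows per treatment
in input order — a deterministic tie-break that preserves block
structure in the sheet.

## Data preparation

Columns are typed A (descriptors), B (quantitative predictors), C
(categoricals), D (responses). The auto-classifier flags identifier
patterns and unique-per-row columns as A, non-numeric or 2–20-level
columns as C, and the numeric remainder as B; *responses are never
auto-assigned* because "high variability" is not a safe criterion —
the user confirms D columns, and user overrides always win.
Categorical levels are integer-encoded 0..L−1 in first-appearance
order (stable across rewrites of the same file, unlike lexicographic
order under renamed levels). Complete-case deletion removes any row
with a missing cell in *any* retained column, descriptors included —
a missing run identifier usually signals a corrupted row, so the
conservative reading costs little. The health check reports IQR
fences at the conventional 1.5 multiplier (type-7 quantiles) and
Pearson correlations over B and D columns only: integer codes carry
no metric, so C columns are excluded from the $|r| > 0.8$
collinearity rule.

## Model building

`split_data()` uses a two-way split with cross-validation standing in
for a separate validation set; the training share is
$\lceil n \cdot 0.75 \rceil$, which reproduces 547/182 on 729 rows and
44/14 on 58. Repeated k-fold CV (default 5 × 3) drives a small grid
search per algorithm; below 50 training rows LOOCV replaces it unless
an explicit fold configuration is given (a stated per-study protocol
outranks the default rule). All nine algorithms sit behind one
fit/predict interface: glmnet (ElasticNet) and FNN (kNN) are used
directly; compiled CART ensembles in `src/` implement the random
forest (200 trees by default — halved from the conventional 500 purely
for single-CPU runtime, accuracy plateaus well before that on these
data sizes) and gradient boosting; PLS (NIPALS), MARS
(forward hinge selection with GCV pruning), ε-SVR (RBF kernel, dual QP
via quadprog) and a single-hidden-layer network (BFGS with weight
decay) are implemented in the package because their usual CRAN homes
are not available in the target environment. The stacked ensemble
(RF + GBT + ElasticNet under a non-negative least-squares meta-learner)
is excluded from the default spot-check roster, as is conventional.
Center-scale preprocessing of predictors is deliberately not applied
globally (tree ensembles are scale-invariant; learners that need
scaling standardize internally and back-transform their predictions),
so decision-space bounds stay in actual units throughout.

Selection is purely data-driven: highest test R², ties broken by lower
test RMSE, then MAE, then algorithm name. Importances are
impurity-based for trees, absolute standardized coefficients for
linear models, and permutation importance (five shuffles on the
training data) otherwise, scaled so the top predictor reads 100 —
note that duplicated predictors split permutation importance between
the twins.

## Optimization

Surrogate predictions are min-max normalized against the observed
response extremes, direction-corrected, and summed into a cumulative
fitness in $[0, n]$. Normalized values are clipped to $[0, 1]$ when a
surrogate extrapolates beyond the observed range — this keeps the
cumulative scale meaningful; the unclipped raw predictions are still
reported per solution. Penalties are $\sum_i w_i \max(0,
\text{violation}_i)$: subtracted from the single objective for GA/PSO,
and coupled into multi-objective selection as constrained domination
(feasible dominates infeasible, smaller violation dominates larger) —
the weight semantics and the multi-objective coupling are package
decisions, since only "penalty-based handling" is standard. The 20%
mutation probability is interpreted per individual with a 1/d per-gene
rate once an individual mutates (the common real-coded convention).
Categorical axes evolve in continuous space and are rounded half-up
only at evaluation, immediately before the surrogate prediction, so
only valid level codes are ever evaluated; the prediction cache keys
on the rounded vector, and disabling it makes the evaluation counter
exactly $\mu + \lambda G$.

NSGA-II uses fast non-dominated sorting with crowding-distance
truncation ($\mu + \lambda$ survival). SMS-EMOA is steady-state
($\lambda = 1$); when the merged population has several fronts it
removes the minimal-hypervolume-contribution member *of the worst
front only* — a documented simplification of the original
dominating-point-count secondary criterion. Its reference point is
fixed at 1.1 per dimension on the internal minimization scale (worst
corrected fitness 1 plus a 10% buffer); for direct benchmark problems
without normalization the reference is re-derived per generation from
the population unless supplied. Hypervolume is exact (dimension-sweep
recursion, a fast staircase path for two objectives); beyond four
objectives a cost warning is emitted but computation proceeds. PSO
uses standard constriction values ($w = 0.729$, $c_1 = c_2 =
1.49445$), velocity clamped at half range with reflecting bounds —
the swarm parameters are package defaults, stated here because no
canonical values exist for this workflow.

Whether reported evaluation totals include cache hits is ambiguous in
general; here the counter counts *model evaluations performed*, so the
published budgets $50 + 20 \times 100 = 2050$,
$50 + 50 \times 150 = 7550$ and $100 + 1 \times 2000 = 2100$ hold
exactly with the cache off, and both penalized and raw fitness appear
in every archive.

## Evaluation

`compare_solutions()` scores original rows on their *observed*
responses and optimized solutions on *predicted* ones, under the
identical objective specs used during optimization; the two columns
are labelled accordingly because conflating measurements with
predictions is the main way such comparisons mislead. Distance
filtering reduces a front to $k$ representatives by greedy max–min
selection in the min-max-scaled decision space seeded at the best
cumulative solution; sequential filtering retains the top
`keep_fraction` per objective in priority order, keeping ties.

## Synthetic generators and what a green test establishes

`make_zdt2()` reproduces the standard two-objective benchmark (750
samples, 10 variables, 10% Gaussian noise by default; "10%" is
operationalized as sd = 0.10 × response sd). `make_tissue4x4()`
emulates a four-input, four-response shoot-proliferation experiment:
bounded logistic-quadratic proliferation rate (5–100% over the box —
flat enough to be learnable from space-filling samples, as real
proliferation data are), peaked quadratic shoot number, a shoot-length
surface whose optimum sits at lower cytokinin than shoot number's (the
classic antagonism), and a monotone callus weight to minimize, with
heteroscedastic Gaussian noise and range clipping. Its factorial
default mirrors the 3⁴ × 9 = 729-row layout of real studies; the
`sampling = "uniform"` mode exists because an *interior* optimum is
not localizable from a 3-level grid (tree surrogates are
piecewise-constant between levels), and the end-to-end recovery test
uses it. The analytic ground truth is the argmax of the true
cumulative fitness, found numerically (dense grid + L-BFGS-B polish)
against true response extremes.

A green recovery test therefore establishes that the pipeline locates
a smooth, moderately noisy interior optimum from space-filling data —
it does not establish performance on heavily replicated grid designs,
on responses with qualitatively wrong surrogates, or under
extrapolation beyond the data, and no synthetic result is evidence
about any published dataset.

## Numerical choices and limitations

Seeds: exactly two (ML and EA) drive all randomness; identical
configuration plus seeds reproduces metrics, archives and exports
bit for bit. Quartiles are type-7; encoding maps are
first-appearance; SBX/mutation clipping is plain truncation to
bounds; cache keys use full-precision coordinates after categorical
rounding. Known limitations: no uncertainty quantification on
surrogate predictions (so densely sampled regions and extrapolations
carry equal apparent confidence), no active learning / sequential
design, exact hypervolume cost grows quickly past four objectives,
and the ε-SVR solves a dense 2n-variable QP, making it the slow entry
of the roster on training sets beyond a few hundred rows.
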