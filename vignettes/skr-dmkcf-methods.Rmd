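---
title: "Methods: Kruskal-RFE feature selection and consensus multi-kernel classification"
author: "skrdmkcf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Kruskal-RFE feature selection and consensus multi-kernel classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skrdmkcf)
```

# The problem

Clinical tabular datasets — diabetes panels, cardiology records, vocal
feature tables, multi-omics matrices — are frequently high-dimensional,
noisy, and class-imbalanced. This package implements a two-stage pipeline
for such data: a hybrid filter/wrapper feature selector, and a multi-kernel
support vector classifier trained by consensus ADMM across simulated
compute nodes.

# Stage one: the Kruskal-RFE selector

## Relevance scoring

Each feature $f_i$ of the $N \times M$ matrix $X$ receives two scores:

* **Variance contribution** $V_i = \frac{1}{N}\sum_j (x_{ij} - \mu_i)^2$,
  the population-variance spread of the feature. One variance convention
  (divide by $N$) is used everywhere in the package, including the z-score
  scaler, so that the scaler and the ranking agree on what "variance" means.
* **Rank separability** $R_i = \sum_c \frac{n_c}{N}(\bar r_c - \bar r)^2$,
  where values are ranked $1..N$ (ties averaged), $\bar r_c$ is the mean
  rank inside class $c$ and $\bar r$ the overall mean rank. With no ties
  this is exactly $H \cdot (N+1)/12$ for the Kruskal–Wallis $H$ statistic,
  so the induced feature ordering is the Kruskal–Wallis ordering; the test
  suite verifies both the identity and the ordering against
  `stats::kruskal.test` on random data. Rank statistics make the score
  robust to outliers and monotone distortions, which matters for
  signal-derived features.

The relevance score is the weighted combination $S_i = \alpha V_i + \beta
R_i$ with defaults $\alpha = \beta = 0.5$. Because $V$ and $R$ live on
incomparable scales, both are min–max rescaled to $[0,1]$ across features
before combining; the literal un-rescaled sum remains available through
`normalize = FALSE`. Whether $\alpha + \beta = 1$ is not enforced — only
nonnegativity with a positive sum.

## Recursive elimination

Starting from all $M$ features, iteration $t$ fits a linear soft-margin SVM
$$\min_{w,b}\ \tfrac12\|w\|^2 + C\sum_j \max(0,\, 1 - y_j(w^\top x_j + b))$$
on the retained columns (through `e1071::svm`, i.e. libsvm) and removes the
$\gamma$ features with the smallest importance $|w_i|$ — the standard
SVM-RFE criterion, where the magnitude of the $i$-th primal component
measures how much the separating hyperplane leans on feature $i$. A
feature-independent norm $\|w\|_2$ would give every feature the same weight
and make elimination undefined, so the componentwise reading is the one
implemented. Ties are broken by lower relevance score $S$, then lower
column index, making the elimination order fully deterministic.

The retained count follows $T_t = T - \gamma t$; the loop halts at `t_max`
iterations or when another batch would drop the count below `T_min`.
Iteration 0 (all features) is always recorded, so an empty schedule
(`t_max = 0`) selects every feature.

Every iteration is scored by the joint objective
$$L = \lambda_1 \cdot \mathrm{relevance} + \lambda_2 \cdot \mathrm{accuracy}
  + \lambda_3 \cdot \mathrm{efficiency},$$
and the first $L$-maximizing iteration's retained set is returned. In the
default *normalized* form all three terms live in $[0,1]$: the mean
relevance score over retained features, a stratified cross-validated
accuracy (3 folds, fixed seed, linear SVM on the retained columns), and
$1 - T/T_{\text{total}}$. The *literal* form uses the raw score sum and
$1/T$. Two choices deserve comment:

* The accuracy term is cross-validated rather than resubstitution, because
  resubstitution accuracy is monotone in feature count and would degenerate
  the trade-off the objective is meant to express.
* The efficiency term is a deterministic function of the retained count
  rather than measured wall-clock time, so $L$ — and therefore the selected
  subset — is reproducible across machines. Wall-clock instrumentation
  lives in a separate reporting utility (`instrumentation()`) and is never
  part of selection.
* The relevance sum runs over the retained features only; summing over all
  $M$ features would make the term constant across iterations.

Defaults, resolved against $M$ at run time: $\gamma = \max(1, \lfloor 0.1
M\rfloor)$, $T_{\min} = \max(2, \lceil 0.05 M\rceil)$, $t_{\max} = 50$,
$C = 1$, $\lambda_1 = \lambda_2 = \lambda_3 = 1$. All are overridable.
Multiclass problems are handled one-vs-rest with per-feature importance the
maximum over the binary problems.

# Stage two: distributed multi-kernel classification

## Composite kernels

The classifier uses a convex combination of base kernels
$K = \sum_m \beta_m k_m$ with $\beta_m \ge 0$, $\sum_m \beta_m = 1$; such a
combination of positive semidefinite kernels is positive semidefinite,
which the suite checks empirically over random simplex draws. The default
base set is linear, polynomial (degree 3, offset 1), and RBF
$\exp(-\|x-x'\|^2/2\sigma^2)$ with $\sigma$ set by the median
pairwise-distance heuristic on a bounded seeded subsample. "Gaussian" and
"RBF" name the same family and are implemented once.

Kernel weights are set by **centered kernel alignment**: each base kernel's
centered Gram matrix is scored by its Frobenius alignment with the ideal
target $yy^\top$ on a bounded subsample (at most 500 points), negative
alignments are clipped to zero, and the result is renormalized onto the
simplex (uniform if all alignments vanish). The alignment depends only on
the data and labels, so although the update formally runs once per outer
training iteration, it is stationary after its first application and is
memoized. Alignment was chosen because it is cheap, deterministic, and
convex-combination-friendly; it is deliberately encapsulated behind
`update_kernel_weights()` so another rule can replace it.

## The shared landmark basis

Summing per-node Gram matrices of unequal sizes is not well defined, so the
distributed design uses a representer basis instead: a common set of $L =
\min(100, N)$ landmark points (seeded uniform subsample of the training
rows) is shared by all nodes, every node computes only its
$|D_j| \times L$ kernel block against that basis, and every coefficient
vector lives in $\mathbb{R}^{L+1}$ (bias last). This keeps node updates
dimension-compatible for consensus averaging regardless of how the samples
are partitioned, at the usual Nystrom-style cost of restricting the
decision function to the landmark span.

## Consensus ADMM

Node $j$ minimizes
$$L_j(\alpha_j) = \tfrac12\|\alpha_j\|^2
  + C\sum_{i \in D_j} \max(0,\, 1 - y_i f(x_i))
  + \rho\,\|z - \alpha_j\|^2,$$
with the ridge taken over the representer coefficients (bias excluded — a
literal dual-variable reading of the quadratic term conflicts with the
proximal consensus formulation) and $f$ parameterized on the shared
landmark basis. The subproblem is solved *exactly* by cyclic dual
coordinate descent on the equivalent box-constrained QP: the quadratic part
is diagonal, each coordinate update is closed-form with clipping to
$[0, C]$, and sweeps stop when the largest projected gradient falls below
$10^{-9}$. The solver is warm-started across outer iterations from the
previous dual variables, which keeps the per-iteration cost low once the
active sets stabilize. The test suite verifies first-order (subgradient)
optimality of the returned minimizer along random directions.

The outer loop is scaled-dual consensus ADMM: each node's proximal center
is the consensus variable shifted by its scaled dual variable, the
consensus update averages $\alpha_j + u_j$, and $u_j \mathrel{+}= \alpha_j
- z$. A plain proximal-averaging loop without dual variables has a fixed
point at the *proximal average* of the node objectives, where the node
coefficients do **not** coincide with the consensus variable; the dual
variables are what drive $\max_j\|\alpha_j - z\|$ to zero, which is the
contract the convergence flag promises. Convergence therefore requires
both $\|z_{t+1} - z_t\| < \varepsilon$ and $\max_j \|\alpha_j - z\| \le
\varepsilon$ (defaults $\varepsilon = 10^{-4}$, at most 100 iterations,
$\rho = 1$). Two standard accelerations are applied on the multi-node
path: over-relaxation (factor 1.6) and residual-balancing adaptation of
the penalty (doubling/halving $\rho$ with the dual variables rescaled
accordingly — the configured $\rho$ is the starting value). With a single
node the recursion reduces to the proximal point algorithm and both are
disabled.

With $P = 1$ and the landmark set equal to the full training set, the
algorithm solves the centralized hinge + ridge problem on the Gram basis;
the suite checks the relative objective gap (at most $10^{-3}$) and
prediction agreement (at least 98%) against an independent interior-point
solve of the dual via `kernlab::ipop`.

Two further determinism choices: training rows are internally sorted into
a canonical order (label, then feature values) before landmark selection
and partitioning, so the fitted model is invariant to the ordering of the
training samples; and stratified partitioning deals each class's shuffled
indices round-robin with a global cursor, so per-node class proportions are
preserved within one sample and block sizes differ by at most one.
Prediction maps a decision score of exactly zero to the positive class.

Distribution is simulated in-process: node updates read only the consensus
state and their own partition, and write only their coefficient vector —
the same contract a networked deployment would honor — but no transport
layer, cluster scheduler or distributed file system is implemented.

# Evaluation metrics

`classification_metrics()` reports accuracy, precision, recall and
specificity from the confusion counts (macro-averaged one-vs-rest beyond
two classes); ratios with a zero denominator are reported as 0 with an
`undefined` flag instead of raising, so batch evaluation never aborts. The
**feature reduction ratio** is kept internally as the *retained fraction*
`n_selected / n_total` — reference result tables report values like
0.87–0.91 on that scale — and is rendered as a percentage only at the
reporting layer. The **relevance score** of a selected subset averages
weight × performance-gain over its features, with the weight taken as the
selector's normalized relevance score and the gain as the add-one-in
cross-validated accuracy delta under fixed folds; neither quantity has a
unique definition in the literature, so both interpretations are
documented here and isolated behind `relevance_score()`. Timing and
memory instrumentation (`instrumentation()`) is hardware-dependent by
nature: it is reported, segregated from deterministic report sections, and
never asserted against in tests.

# The synthetic-data generator

`generate_dataset()` emulates four archetypes with a known ground truth:

* informative features are class-conditional Gaussians with unit
  within-class standard deviation and mean gap `effect` (default 1.5), so
  the standardized effect size is exact by construction and analytic
  expectations are available to the tests;
* noise features are label-independent standard normals;
* redundant features are an informative parent plus $N(0, 0.5)$ noise,
  giving parent correlation $1/\sqrt{1.25} \approx 0.89 \ge 0.8$;
* labels are binary with the minority fraction equal to `imbalance`, exact
  up to rounding;
* the `signal` archetype passes features through the bounded nonlinear
  mixture $x + 0.75\sin(2x)$, breaking linearity while keeping rank
  structure; the `categorical_mixed` archetype converts trailing columns to
  3-level quantile codes; `highdim` enforces $p \ge 5n$.

The canonical `fixture_suite()` mirrors familiar public-benchmark shapes
(768×8, 300×13, 195×22, 100×2000 at imbalance 0.3) purely as recognizable
scales. What the generator does *not* emulate — and what passing tests on
it therefore cannot show — includes missing data, measurement batch
effects, heavy-tailed or mixed-type noise, label noise, and realistic
feature dependence beyond the explicit redundant blocks. Results on
synthetic archetypes demonstrate algorithmic correctness, not clinical
performance.

# Problem sizes and numerical tolerances

The shipped tests and the acceptance script run at deliberately modest
scales chosen as representative rather than exhaustive: 50–60 random
datasets (N ≤ 30) for the rank-statistic equivalence, 20 seeds of a
300 × 50 recovery problem for the selector, blob fixtures of 120–200
samples for the classifier contracts, and a single 100 × 500
high-dimensional selection run. Key tolerances: rank-statistic identity
1e-9; inner QP projected-gradient 1e-9 (asserted first-order optimality
1e-5); ADMM convergence 1e-4 on both residuals; centralized objective gap
1e-3; composite-kernel minimum eigenvalue −1e-8.

# Known limitations

* The selector's accuracy term refits an SVM per iteration and fold; for
  very large $M$ with small $\gamma$ the quadratic number of fits
  dominates. Choose a larger $\gamma$ or smaller `t_max` there.
* The landmark basis bounds model capacity by $L$; severely multimodal
  decision boundaries may need `n_landmarks` above the default 100.
* Kernel weights are filter-style (alignment), not jointly optimized with
  the classifier objective; a wrapper-style update would be costlier but
  possibly better calibrated.
* Base kernels of wildly different numeric scale (e.g. a high-degree
  polynomial next to an RBF) make the consensus problem ill-conditioned
  and slow its tail convergence; if exact consensus at tight tolerance is
  needed, prefer comparable-scale kernels or raise `max_iter`.
* Multiclass classification is delegated to one-vs-rest wrapping by the
  caller; only the binary core is implemented.
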