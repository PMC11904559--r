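# skrdmkcf

Feature selection and distributed multi-kernel classification for
high-dimensional clinical tabular data.

Medical tabular datasets (diabetes panels, cardiology records, vocal
feature tables, multi-omics matrices) are typically high-dimensional,
noisy and class-imbalanced. This package implements a two-stage pipeline
for such data, aimed at analysts who need a reproducible, seedable
selection-plus-classification workflow that runs on a single machine while
exercising the same algorithmic structure as a distributed deployment.

**Stage 1 — Kruskal-RFE selector.** Each feature receives a relevance
score

  S_i = α·V_i + β·R_i,

where V_i = (1/N) Σ_j (x_ij − μ_i)² is the population variance and
R_i = Σ_c (n_c/N)(r̄_c − r̄)² is a Kruskal-Wallis-type rank separability
statistic (with no ties, R = H·(N+1)/12 for the Kruskal-Wallis H; both are
min–max normalized before combining). Recursive feature elimination then
repeatedly fits a linear soft-margin SVM and removes the γ features with
smallest primal-weight magnitude |w_i|, following the schedule
T_t = T − γ·t. Every iteration is scored by a joint objective

  L = λ₁·relevance + λ₂·CV-accuracy + λ₃·efficiency,

and the first L-maximizing retained set is selected.

**Stage 2 — distributed multi-kernel classifier.** A composite kernel
K = Σ_m β_m k_m (simplex weights over linear / polynomial / RBF, set by
centered kernel alignment) parameterizes a hinge-loss classifier
f(x) = Σ_l z_l K(x, x_l) + b on a shared landmark basis. Training is
consensus ADMM across P simulated nodes: each node exactly solves its
ridge + hinge + proximal subproblem by dual coordinate descent, the
consensus variable is the (dual-shifted) average of the node coefficients,
and convergence requires both the consensus-variable change and the worst
node residual max_j‖α_j − z‖ to fall below ε.

Evaluation utilities cover accuracy/precision/recall/specificity, the
feature reduction (retained-fraction) ratio, an ablation-based relevance
score, and timing instrumentation, plus a seeded synthetic-data generator
for four clinical data archetypes with known informative-feature masks.

## Worked example

```r
library(skrdmkcf)

# 300 samples, 50 features of which 5 are informative (effect size 1.5)
ds  <- generate_dataset(generator_spec("numeric", n = 300, p = 50,
                                       p_informative = 5, seed = 1))
ds  <- preprocess(ds)                          # z-score, population sd
sel <- skr_select(ds, ranking_weights(0.5, 0.5), rfe_config(seed = 1))
print(sel)
#> <skr_selection> 5 of 50 features selected
#>   features: f1, f2, f3, f4, f5
print(sel$trace)
#> <selection_trace> 10 iterations, retained 50 -> 5 features
#>   best: iteration 10 (t=9), 5 features, L = 2.5618
feature_reduction_ratio(length(sel$selected), ncol(ds$X))
#> [1] 0.1

sub   <- skr_dataset(ds$X[, sel$selected], ds$y, preprocessed = TRUE)
model <- dmkcf_fit(sub,
                   composite_kernel(list(kernel_spec("linear"), kernel_spec("rbf"))),
                   dmkcf_config(P = 2, max_iter = 400))
print(model)
#> <dmkcf_model> 100 landmarks, 2 nodes, 2 kernels, converged after 254 iterations
#>   beta: 0.496, 0.504
mean(predict(model, sub) == sub$y)
#> [1] 0.9633333
```

The selector recovers exactly the five planted informative features
(`f1`–`f5`, a retained fraction of 0.10), and the two-node consensus fit
converges with near-uniform kernel weights and 96% training accuracy.

## Command line

A thin wrapper at `inst/cli/skr-dmkcf` exposes the same pipeline as
`simulate`, `select`, `train`, `evaluate` and `benchmark` subcommands
(`--key value` options, optional `--config file.json`, one `--seed` fixing
every stochastic stage; exit status 0/2/1 for success / usage error /
runtime error):

```sh
Rscript inst/cli/skr-dmkcf simulate --archetype highdim --n 100 --p 500 --seed 7 --out data.csv
Rscript inst/cli/skr-dmkcf select   --input data.csv --seed 7 --out-dir selection/
Rscript inst/cli/skr-dmkcf train    --input selection/selected.csv --nodes 4 --seed 7 --model-out model.json
Rscript inst/cli/skr-dmkcf evaluate --input selection/selected.csv --model model.json --out-dir report/
```

Reports are deterministic given the configuration; timing is segregated
into `report_timing.json`.

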