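# dpcollab

Collaborative learning from distributed health data via differentially
private synthetic cohorts.

## The problem

Multiple parties — hospital sites, biobank assessment centers — each hold a
small, sensitive cohort of categorical records and want population-level
estimates from an analysis model, but cannot pool their raw data. Each
party's local data may also be *skewed*: disjoint, non-uniform samples of
the population with `Pr[x | center] ≠ Pr[x]`. `dpcollab` implements and
evaluates a coordination-free alternative to federated learning: every party
fits a generative model to its local data under differential privacy,
publishes K synthetic replicates, and then fits the analysis model on its
own real records combined with everyone else's synthetic ones.

The package is for biostatisticians and privacy researchers who want a
fully reproducible, testable simulation of this protocol with known ground
truth — including the hard regimes where it earns its keep: a few hundred
records per party, strict privacy (ε = 1, δ = 10⁻⁶), and deliberately
injected local distribution skew.

## The models

**Analysis task** — Poisson regression of a binary test outcome on d
categorical covariates (dummy-encoded vector x̃):

    f(x; w) = argmax_{y ∈ {0,1}} λ^y e^{-λ} / y!,   λ = exp(wᵀ x̃)

**Generative model** — a mixture of product-categoricals for the covariates
plus the same Poisson regression for the outcome:

    p(x | θ, π) = Σ_{r=1}^{R} π_r Π_{j=1}^{d} p(x_j | θ_j^{(r)}),
    p(y | x, w) = λ^y e^{-λ} / y!

Each party infers a mean-field variational posterior over (π, θ, w) with
DP-SGD (per-example gradient clipping to norm C, Gaussian noise σC,
Poisson-subsampled batches), with the total (ε, δ) tracked by a numerical
privacy-loss-distribution accountant (FFT composition, RDP cross-check).
Replicates are combined downstream with the fully-synthetic-data variant of
Rubin's rules,

    w̄_K = mean(w_k),   v̂_K = (1 + 1/K) b − v̄   (conservative + fallback when negative),

and models are scored by Monte-Carlo predictive log-likelihood on a global
held-out test set, with Welch's t-test on pooled mid-ranks for comparisons.

## Worked example

A compact study: 4 simulated centers (~2,400 records each, heterogeneous),
local training data subsampled to 25%, privacy target ε = 1, δ = 10⁻⁶,
K = 20 synthetic replicates per party:

```r
library(dpcollab)

cfg <- experiment_config(
  cohort = cohort_config(n_population = 12000, n_centers = 4, seed = 42),
  train_fraction = 0.25, epsilon = 1, delta = 1e-6,
  k_replicates = 20, n_repeats = 2, n_permutations = 5,
  vi_iterations = 1500, seed = 42)

state  <- prepare_study_state(cfg)   # DP fits + releases, per repeat/center
glance(state$repeats[[1]][[1]]$posterior)
#>   n_par mixture_components n_train epsilon    delta noise_multiplier ...
#> 1   203                 16     268   1.000 0.000001             61.1

result <- run_combined_vs_local(cfg, state)
dplyr::summarise(dplyr::group_by(result, center, condition),
                 median_loglik = median(loglik), .groups = "drop")
#>   center condition median_loglik
#> 1      1 combined         -0.420
#> 2      1 local            -0.472
#> 3      2 combined         -0.418
#> 4      2 local            -0.424
#> 5      3 combined         -0.421
#> 6      3 local            -0.433
#> 7      4 combined         -0.421
#> 8      4 local            -0.439
#> 9     NA pooled           -0.415

summarize_significance(result)
#>   center statistic    df   p_value   n_a   n_b alternative
#> 1      1     30.7   398. 3.91e-107   200   200 greater
#> 2      2      7.21  397. 1.45e- 12   200   200 greater
#> 3      3     14.2   397. 1.18e- 37   200   200 greater
#> 4      4     17.6   398. 8.03e- 52   200   200 greater
```

Reading the output: the posterior `glance` shows the privacy ledger of one
party's fit — 268 local training records, noise multiplier 61.1 calibrated
so the realized ε is 1.000 at δ = 10⁻⁶. In the result table, every center's
median normalized test log-likelihood improves when synthetic data from the
other three parties is combined with its local records (e.g. center 1:
−0.472 → −0.420), approaching the privacy-agnostic pooled-data ideal
(−0.415), and each improvement is highly significant under the one-sided
ranked Welch test. `autoplot(result)` draws the per-center box plots.

Other experiment drivers: `run_incremental()` (parties added one at a
time), `run_size_sweep()` (training-set size grid), `run_skew_experiment()`
(an artificial population-matched party with a depleted
minority-category × outcome cell, evaluated on that subgroup). A thin CLI
over these functions lives at `inst/cli/dpcollab.R`.

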