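# scoreDA

Differential abundance testing for compositional high-throughput
sequencing data — microbial amplicon profiles, single-cell RNA-seq
cell-type compositions — with explicit feature interactions.

## Why

Relative abundance data live on the probability simplex: only ratios
carry information, and a condition effect on one feature drags every
correlated feature with it. Per-feature tests mistake these secondary
shifts for real effects and inflate the false discovery rate. `scoreDA`
fits a generative model that estimates pairwise feature interactions
*jointly* with the condition effect, so the test asks whether a feature
moved beyond what its interactions explain.

## The model and estimator

Each sample x on the simplex with covariate y follows the
covariate-extended power interaction density

    p(x | y)  ∝  exp{ −½ u_a(x)ᵀ K u_a(x) + (η₀ + y η₁)ᵀ u_b(x) },
    u_c(x) = (x^c − 1)/c   (log x at c = 0),

with symmetric interaction matrix K and location vectors η₀ (baseline)
and η₁ (covariate effect). At a = b = 0 the family contains the
Dirichlet and logistic normal distributions; positive powers handle
exact zeros without imputation.

The normalizing constant is intractable, so parameters are estimated by
l1-penalized generalized score matching: the empirical loss is an exact
quadratic ½θᵀΓθ − gᵀθ in θ = (vec(K), η₀, η₁), solved by proximal
coordinate descent along a warm-started penalty path, with λ₁ chosen by
5-fold cross-validation (1SE rule) or eBIC. Differential abundance of
feature j is tested with the studentized statistic
T_j = η̂₁ⱼ / √Ŝ_{η₁ⱼ} using a sandwich variance estimate, referred to
t(n − 3), with Benjamini–Hochberg adjustment. A Procrustes-alignment
scheme (`selectPower()`) picks the power exponent φ = a = b that best
matches the additive log-ratio geometry of the data.

The package also ships the simulators and benchmark harnesses for the
method's synthetic studies: banded interaction matrices, an exact
logistic-normal sampler for the log-based subfamily, a pairwise Gibbs
sampler for the general model, support-recovery ROC/AUC, and two-group
DA scenarios with FDR/TPR/MCC scoring.

## Worked example

Simulate a two-group scenario on p = 11 correlated features in which
only feature 8 responds to the condition (effect size τ = 1, so
η₁,₈ = η₀,₈ ≈ −1.40), then run the full pipeline:

```r
library(scoreDA)
set.seed(1)
scen <- makeDAScenario(n = 1000, tau = 1, targetFeatures = 8)
run <- runDA(scen$dataset, runConfig(a = 0, b = 0, lambdas = daLambdaGrid()))
subset(daTable(run$results), !is_reference,
       select = c(feature, eta1_hat, se, t, p_adj))
```

```
     feature     eta1_hat        se           t        p_adj
1   feature1 -0.045860100 0.2569968 -0.17844620 9.716160e-01
2   feature2 -0.017458231 0.2707856 -0.06447253 9.716160e-01
3   feature3  0.016221439 0.2776895  0.05841573 9.716160e-01
4   feature4  0.458300210 0.2580791  1.77581297 3.803436e-01
5   feature5  0.157083642 0.2201586  0.71350208 9.716160e-01
6   feature6  0.045723540 0.2003567  0.22821074 9.716160e-01
7   feature7 -0.046590207 0.1633102 -0.28528652 9.716160e-01
8   feature8 -0.773041253 0.1321559 -5.84946241 6.681621e-08
9   feature9  0.005181581 0.1455889  0.03559050 9.716160e-01
10 feature10  0.056498811 0.1560160  0.36213479 9.716160e-01
```

Only feature 8 is called (adjusted p = 6.7e-08; the penalized estimate
η̂₁,₈ = −0.77 is attenuated relative to the true −1.40 but carries the
right sign and dominates its standard error). Every other feature shifts
visibly in the raw proportions — they are correlated with feature 8
through the interaction matrix and through compositional closure — but
the model attributes those shifts to K rather than to the condition. On
the same data, the naive per-feature t-test on log proportions
(`logTTestDA(scen$dataset)`) declares nine of the ten testable features
differentially abundant at the same level: eight false positives.

The reference feature (profiled out of the model, by default the last
column; pick a high-abundance, low-variance feature) carries no test.

## Command line

A thin CLI over the package functions is installed with it:

```sh
Rscript $(Rscript -e 'cat(system.file("scripts", "scoreda.R", package = "scoreDA"))') \
  test --table abundance.tsv --metadata metadata.tsv --covariate group \
  --power auto --out results/
```

Subcommands: `test` (end-to-end DA), `fit` (interaction matrix only),
`select-power`, `simulate`, `evaluate`. Exit code 2 on validation
errors.

## Documentation

The methods vignette (`vignettes/score-matching-da.Rmd`) describes the
model and its assumptions, the score matching system and its oracle
tests, the solver, the sandwich test and its calibration conventions,
the power-tuning procedure, the samplers, and known limitations.
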