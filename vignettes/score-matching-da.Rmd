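---
title: "Differential abundance with power interaction models and penalized score matching"
author: "scoreDA package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential abundance with power interaction models and penalized score matching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scoreDA)
```

## The problem

Relative abundance matrices from high-throughput sequencing — microbial
taxa from 16S amplicon data, or cell-type proportions from clustered
single-cell RNA-seq — are compositional: each sample is a point on the
probability simplex, and only ratios carry information. When a condition
perturbs one feature, every correlated feature shifts with it, both
through biological interactions and through the sum-to-one constraint.
Per-feature differential abundance (DA) tests cannot tell these secondary
shifts from primary effects and flag them as false discoveries.

`scoreDA` addresses this by fitting a *generative* model that carries an
explicit feature-interaction matrix alongside the covariate effect, so
that the condition effect on each feature is estimated conditionally on
the interactions.

## The model

Each sample $x \in \Delta^{p-1}$ with covariate value $y$ (binary group
indicator or continuous) is modelled by the covariate-extended power
interaction density

$$
p(x \mid y) \;\propto\; \exp\Big\{ -\tfrac12\, u_a(x)^\top K\, u_a(x)
 \;+\; (\eta_0 + y\,\eta_1)^\top u_b(x) \Big\},
\qquad u_c(x) = \frac{x^c - 1}{c}\ \ (\log x \text{ at } c = 0),
$$

with a symmetric interaction matrix $K$ ($K 1_p = 0$ for ground-truth
parameters), a baseline location vector $\eta_0$, and a covariate effect
$\eta_1$ on the location. At $a = b = 0$ the family contains the
Dirichlet ($K = 0$), the logistic normal, and Aitchison's distribution
class on the simplex; positive powers extend the model continuously to
data with exact zeros, removing the need for zero imputation.

**Centered transform.** We use the Box–Cox-type centered statistic
$u_c(x) = (x^c - 1)/c$ throughout, rather than $x^c/c$. Because constant
shifts of the statistic leave the $K$-quadratic invariant when
$K 1_p = 0$ and only change the location term by a constant absorbed into
the normalizing constant, the model family is unchanged (with $K$
rescaled by $c$ relative to the uncentered convention; the two agree
exactly at $c = 0$ and $c = 1$). The payoff is numerical: $u_c \to \log$
smoothly as $c \to 0$, so small powers behave like the log model instead
of overflowing. A unit test asserts agreement of the $a = 10^{-6}$ and
$a = 0$ densities to $10^{-3}$.

## Estimation: generalized score matching

The normalizing constant of the density is intractable, so maximum
likelihood is unavailable. Estimation minimizes the weighted Hyvärinen
divergence between model and data scores. After profiling out a
reference coordinate ($x_p \equiv 1 - \sum_{j<p} x_j$, analogous to an
additive log-ratio reference) and choosing the boundary weight
$\tilde h_j(x) = \min\{x_j, x_p, C_j\}^c$ (defaults $C_j = 1$, $c = 2$),
the empirical loss is, per sample and coordinate,

$$
\tfrac12\,\tilde h_j (\partial_j \log p)^2
 + (\partial_j \tilde h_j)(\partial_j \log p)
 + \tilde h_j\, \partial_{jj} \log p ,
$$

averaged over samples. Both partial derivatives are *linear* in
$\theta = (\mathrm{vec}(K), \eta_0, \eta_1)$, so the loss is the
quadratic $\tfrac12 \theta^\top \Gamma \theta - g^\top \theta$.
`buildScoreSystem()` assembles $\Gamma$ and $g$ by collecting the sparse
coefficient rows of those partials — no transcribed closed forms — and a
test suite asserts, over random datasets and parameter draws, that the
quadratic form equals the directly evaluated loss (`lossDirect()`) to
$10^{-8}$. This makes the system construction self-verifying. The
covariate blocks are $y$-weighted averages of the baseline blocks and
fall out of the same construction.

The weight derivative at the kink $x_j = x_p$ uses the derivative of the
active branch with ties resolved toward the $x_j$ branch (a
measure-zero event); the $x_p$ branch carries a $-1$ chain factor from
the profiled coordinate.

**Diagonal multiplier.** In the high-dimensional regime
($r = p^2 + 2p$ exceeding the $n(p-1)$ stacked score rows) the
$\ell_1$-penalized problem can be unbounded; the $\Gamma$ diagonal
entries of the vec($K$) block are then multiplied by
$\delta = 2 - \big(1 + 4e\max\{\sqrt{6\log(p)/n},\, 6\log(p)/n\}\big)^{-1} > 1$
during optimization, which also resolves the exact column collinearity
of the $(j,k)$ and $(k,j)$ coordinates of vec($K$); estimates are
symmetrized on output. The multiplier perturbs the estimating equations
— it solves $\Gamma_\delta\theta = g$ rather than $\Gamma\theta = g$ —
and therefore biases estimates at finite $n$ (empirically, a
two-target effect of $\mp 0.7$ on $\eta_1$ is recovered as roughly
$\mp 0.55$ at $\delta = 1.25$ even with $n = 16{,}000$ samples, and
exactly at $\delta = 1$). The "auto" rule therefore applies the
inflation formula only when $n(p-1) < 2r$ and uses $\delta = 1$ in the
overdetermined regime typical of differential abundance testing, where
boundedness is not at risk. $\delta$ remains a configurable argument
throughout.

## Optimization

`cdFit()` minimizes
$\tfrac12\theta^\top\Gamma_\delta\theta - g^\top\theta
 + \lambda_1\|\mathrm{vec}(K_{\mathrm{off}})\|_1
 + \lambda_2(\|\eta_0\|_1 + \|\eta_1\|_1)$
by cyclic proximal coordinate descent (soft-thresholding updates; the
diagonal of $K$ and, by default, $\eta$ are unpenalized). Because the
loss depends on the mirrored $(j,k)$ and $(k,j)$ coordinates of
vec($K$) only through structurally identical $\Gamma$ columns, the
solver updates each mirror pair as one fused symmetric coordinate with
penalty $2\lambda_1$ — exactly equivalent to the per-coordinate scheme
where that scheme's solution is unique, canonical (symmetric) where it
is not, and half the sweep cost. The sweep terminates when the largest
coordinate change drops below
$\varepsilon \cdot \max(1, \|\theta\|_\infty)$; the interactive default
is $\varepsilon = 10^{-1}$ with at most 1000 sweeps (ill-conditioned
small-sample systems may need more sweeps to reach tight tolerances).
After each full sweep the solver iterates on the current active set
until it settles, then confirms with another full sweep — the standard
path-solver strategy. Unit tests check the KKT subgradient conditions at solutions,
agreement of the unpenalized fit with a dense linear solve, objective
monotonicity per sweep, and invariance to the coordinate update order.

**Benchmark accuracy.** The replicate-level benchmark harnesses fit
paths at $\varepsilon = 10^{-3}$: support-recovery AUC on a fixed
replicate moves from 0.732 at the loose interactive default to 0.756 at
$10^{-3}$ and is unchanged at $10^{-4}$, i.e. the reported supports are
those of converged minimizers.

**Penalty path.** The default grid is 100 log-linearly spaced values on
$[10^{-6}, 1]$. The path is meant to cover the whole sparsity range of
$K$, from diagonal-only to dense, and the penalty scale at which that
happens depends on the data dimensions; the harnesses therefore
interpret the grid as fractions of the data-dependent smallest fully
sparsifying penalty (`lambdaMaxSparsify()`; `scaleToLambdaMax = TRUE` in
`fitPath()`). Warm starts run from sparse to dense, optionally stopping
early once the support is complete.

## Model selection

`crossValidate()` performs $k$-fold CV ($k = 5$ default) on the
*unpenalized* validation loss
$\tfrac12\theta^\top\Gamma_{\mathrm{val}}\theta - g_{\mathrm{val}}^\top\theta$
(the $\delta$ multiplier is an optimization device, not part of the
divergence, so it is omitted from validation). The default rule is the
one-standard-error rule: the largest $\lambda_1$ within one SE of the CV
minimum. Fold assignment ignores the covariate by default; stratified
assignment for binary covariates is available.

An eBIC-type criterion is provided as an alternative:
$S\log(n) - 2\log(\hat L + \mathrm{shift}) + 2\gamma\|\mathrm{vec}(\hat
K_{\mathrm{off}})\|_1$ with $S$ the off-diagonal support size and
$\gamma = 0.5$ by default. The model has no tractable likelihood, so the
quadratic score matching loss is plugged into the log-likelihood slot;
since that loss can be nonpositive, `selectLambdaEBIC()` shifts it by
the path-wide minimum plus one before taking the log (the raw printed
form, using the penalized objective, is available behind
`useRawLoss = TRUE`). This surrogate is heuristic and is not used on any
benchmark surface in this package.

## Differential abundance testing

With $\hat\theta$ from the penalized fit, the per-sample estimating
scores $\psi_i = \tilde\Gamma_\delta^{(i)}\hat\theta - \tilde g^{(i)}$
give $\widehat\Sigma_0 = \tfrac1n\sum_i \psi_i\psi_i^\top$ and the
M-estimation sandwich
$\widehat S = \Gamma^{-1}\widehat\Sigma_0\Gamma^{-1}/n$ for
$\mathrm{Var}(\hat\theta)$; the outer inverse uses the unscaled
$\Gamma$, with a ridge jitter of $10^{-8}\,\mathrm{tr}(\Gamma)/r$ when
the condition number exceeds $10^{12}$ (the $\delta$-scaled variant is
available for parity experiments). The studentized statistic
$T_j = \hat\eta_{1,j}/\sqrt{\widehat S_{\eta_{1,j}}}$ is referred to a
$t$ distribution with $n - 3$ degrees of freedom (fixed, independent of
$p$ and of the selected support), two-sided; p-values are
Benjamini–Hochberg adjusted across the non-reference features. The
profiled-out reference feature carries no test.

Two empirical checks back the approximation under the simulation model:
the Monte-Carlo standard deviation of $\hat\eta_1$ over replicates
matches the mean reported SE within a few percent at small $\lambda_1$,
and pooled null statistics pass a Kolmogorov–Smirnov test against
$t_{n-3}$ with nominal type-I error. Both checks fit with
$\lambda_1 = 1/n$: the $t$ approximation is an asymptotic statement
about the (vanishing-penalty) M-estimator, and at fixed larger
$\lambda_1$ the test becomes visibly conservative. Standard errors are
computed at the penalized estimate without post-selection adjustment;
this caveat is inherent to the approach.

## Choosing the power exponent

For zero-rich data the log model requires zero replacement, which
distorts compositions. `selectPower()` instead tunes a single exponent
$\phi = a = b$ on the raw data: for each candidate $\phi$ it computes
the Procrustes correlation between (i) the column-centered Box–Cox-type
compositional transform
$X_{\phi, j} = \tfrac1\phi\big(p X_j^\phi / \sum_k X_k^\phi - 1\big)$
of the unmodified data and (ii) the column-centered ALR transform of
zero-replaced data (pseudocount 0.5 on the count scale; a zero column is
appended at the reference so dimensions match), and selects the
$\phi^\ast$ maximizing the correlation (grid $0.01, \dots, 0.99$;
smallest $\phi$ on ties). Procrustes alignment over full-dimensional
rotations is invariant to orthogonal changes of basis, so aligning the
centered matrices is equivalent to aligning complete principal-component
embeddings; an explicit truncated PCA variant is available via `nPC`.
On strictly positive data generated from the log model the selected
power lands in the lower third of the grid, as expected.

When only proportions are available the pseudocount is applied as
`pseudocount / median(libSizes)` if library sizes are supplied, and as
half the smallest positive proportion otherwise.

## Simulators

`bandedInteractionMatrix(p, s)` builds the ground-truth
$K_{ij} = |i - j|/(s + 1) - 1$ inside the band, diagonal equal to the
negative off-diagonal row sums — symmetric, diagonally dominant,
positive semidefinite, $K 1_p = 0$.

**Exact sampling.** For $a = b = 0$, $K 1_p = 0$ and
$1_p^\top \eta = -p$, write $w_j = \log(x_j/x_p)$. A change of variables
shows the density of $w$ is proportional to
$\exp\{-\tfrac12 w^\top \tilde K w + (\eta_{-p} + 1)^\top w\}$ with
$\tilde K = K_{-p,-p}$: the Jacobian $\prod_j x_j$ contributes
$1^\top w + p \log x_p$, and $x_p^{\,1^\top\eta}$ cancels it exactly
when $1^\top\eta = -p$. The model is then *exactly* a logistic normal,
$w \sim N(\tilde K^{-1}(\eta_{-p}+1),\, \tilde K^{-1})$, and sampling is
a Cholesky draw. The recovery benchmark ($\eta_0 = -1_p$) and the
control groups of the DA scenarios satisfy these conditions, so those
datasets are exact draws, not MCMC output.

**Gibbs sampling.** Outside that subfamily (e.g. case groups, whose
$\eta_0 + \eta_1$ breaks the sum condition, or any $a, b > 0$), a
pairwise Gibbs sampler runs parallel chains: each sweep redistributes
mass within $\lfloor p/2\rfloor$ disjoint random coordinate pairs, which
keeps the simplex constraint exact, and draws the univariate conditional
over the pair fraction $\xi = x_j/(x_j + x_k)$ by griddy inverse-CDF.
The grid is *logit-spaced* (256 midpoints over
$\mathrm{logit}(\xi) \in [-12, 12]$, weighted by the Jacobian
$\xi(1-\xi)$, with uniform jitter within the selected logit bin): log
model conditionals concentrate near the boundary, and a uniform
$\xi$ grid under-resolves that region badly enough to bias stationary
moments. Defaults are one chain per requested draw with 1000 burn-in
sweeps; chains warm-start from the ALR-Gaussian approximation when
$K_{-p,-p}$ is positive definite. Validation is against closed forms
and the exact sampler rather than another MCMC implementation:
Dirichlet marginal moments at $K = 0$ within Monte-Carlo error, a
total-variation comparison ($< 0.05$) of a $p = 3$, $a = b = 1$ chain
against quadrature of the target density, and agreement of ALR moments
with the exact logistic-normal draw on the scenario base parameters.

**DA scenarios.** `makeDAScenario()` draws $n/2$ control samples from
$(K_B, \eta_{0,B})$ and $n/2$ case samples from
$(K_B, \eta_{0,B} + \eta_{1,B})$ with
$\eta_{1,B} = \tau\, i \odot \eta_{0,B}$, $\tau \in
\{-0.5, -0.3, 0.3, 0.5, 1\}$ and $i$ the indicator of affected
features. The shipped base parameters are a *synthetic* stand-in for
base parameters estimated from real cell-type data (which are published
only as a figure): a bandwidth-2 banded matrix plus a
centered-projection ridge, $K_B = K_{\mathrm{band}} + 0.5(I - J/p)$ on
$p = 11$ features, and $\eta_{0,B} = -1_p + 0.4\sin(2\pi j/p)$, whose
perturbation sums to zero (keeping the control group exactly
sampleable). The ridge keeps $K_B 1_p = 0$ while bounding the log-ratio
variances; the implied moments (ALR means within about $\pm 1$,
standard deviations near 1, neighbour correlations 0.6–0.8) are typical
of cell-type composition data, whereas the un-ridged banded matrix is
nearly singular off the constant direction and degenerates to extreme
compositions that carry almost no information about $\eta$. All DA
benchmark checks are property-based (FDR orderings), not
value-matching, because the true base parameters are figure-only.
`tileBlockDiagonal()` scales the scenario to $p = 99$.

## Benchmarks and what they show

`runRecoveryBenchmark()` reproduces the interaction-recovery study:
$R$ replicates of $n$ samples at $p = 100$ from the banded-$K$ log
model, fitted (i) without covariate, (ii) with a deliberately
misspecified binary covariate, and (iii) by graphical lasso on
CLR-transformed data (a thin comparator written for this package and
checked against its KKT conditions; it operates on the covariance of
the CLR data, the SPIEC-EASI convention). Supports along the shared
100-value path are scored against the true $K$ by ROC with (0,0)/(1,1)
anchors and trapezoid AUC; replicate curves are averaged vertically on
a common FPR grid. The desk-scale problem sizes are $R = 5$, $n = 80$,
$s = 2$ (low-$n$ design) and a single replicate of the $n = 1000$,
$s = 7$ high-$n$ design for the method-ordering check; the ordering
(score matching above the glasso comparator) only emerges in the
genuinely high-$n$ regime — at $n = 400$ the comparator still matches
the score matching fits.

`daBenchmark()` runs the two-group scenarios across the $\tau$ grid and
compares the full pipeline (5-fold CV with the 1SE rule on the 20-value
$[10^{-3}, 2]$ scenario grid, sandwich test, BH at $\alpha = 0.05$)
against the interaction-blind baseline of per-feature Welch $t$ tests on
log proportions. The headline property is the FDR ordering: modelling
$K$ removes most of the secondary-effect false discoveries that the
naive test makes on correlated features. The default scenario places the
effect on the most strongly loaded feature (largest $|\eta_{0,j}|$, so
the relative effect $\tau\,\eta_{0,j}$ is largest) — the analogue of an
abundant cell type. The ordering property is only meaningful when the
scenario carries detectable signal: on the weakest-loaded features the
effect sizes $\tau\,\eta_{0,j}$ fall below one standard error of
$\hat\eta_1$ at these sample sizes, both methods make few or no calls,
and the comparison degenerates to ties.

Because the generator *is* the model, these benchmarks validate
estimation and inference under correct specification (plus the
misspecified-covariate and glasso arms). They do not capture count
noise at finite sequencing depth, zero inflation beyond what the power
model induces, or overdispersion across biological replicates — on real
data the DA results should be read with those caveats, and the power
exponent tuned with `selectPower()` rather than fixed at the log model.

## Degenerate inputs and numerical conventions

Zeros are admissible only for $a, b > 0$; log models stop with a
pointer to the pseudocount option (0.5 by default, behind an explicit
flag). Stacked coordinate rows whose weight and weight-derivative both
vanish ($x_j = 0$ or $x_{\mathrm{ref}} = 0$) contribute nothing and are
zeroed before assembly. Non-finite system entries (extreme powers)
raise an error naming the offending feature. Dense storage of $\Gamma$
grows as $(p^2 + 2p)^2$; a memory guard refuses $p > 150$ with advice
to filter features. Propriety of $a = 0$ parameter sets is checked on a
finite grid of simplex points — a necessary condition only, as the
quadratic-form condition cannot be certified by sampling.

## Session info

```{r}
sessionInfo()
```
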