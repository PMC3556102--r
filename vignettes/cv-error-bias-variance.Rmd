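---
title: "Bias and variance of cross-validation error estimators: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bias and variance of cross-validation error estimators: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cvbias)
```

## The estimation problem

A classifier trained on a sample of size $n$ has a *true conditional error*:
the probability that this particular trained rule misclassifies a new
observation. Resampling estimators — leave-one-out, repeated $k$-fold
cross-validation, and bootstrap cross-validation (BCV), in which a
with-replacement resample of the data is itself cross-validated — are
routinely used to estimate it. `cvbias` rebuilds the Monte Carlo experiment
that measures how well they do, decomposing each estimator's mean squared
error into a within-run variance and a squared-bias part, and reproducing
the central finding: BCV buys its lower between-run spread with a negative
bias that becomes severe as dimension grows, because a bootstrap test point
has probability $1-(1-1/n)^n \approx 0.632$ of also appearing in its
training set.

## Population model and estimand

Two Gaussian classes in $p$ dimensions: class 1 is $N(0, I_p)$ and class 2
is $N(\mu_2, \Sigma_2)$ with $\mu_2 = (\Delta/\sqrt p)\,\mathbf 1_p$, so
$\lVert\mu_2\rVert = \Delta$ in every dimension and the equal-covariance
Bayes error is $\Phi(-\Delta/2)$ regardless of $p$. The covariance is
$\Sigma_2 = I_p$ (equal case) or $2 I_p$ (unequal case). The published form
of $\mu_2$ is typographically garbled; the $(\Delta/\sqrt p)\,\mathbf 1_p$
reading is the one under which the reported mean true errors approach
$\Phi(-\Delta/2)$ for both $p=1$ and $p=5$, and it is what
`population_config()` implements.

Rather than an infinite population, a *super-population* of 10,000 points
(5,000 per class) is drawn once per configuration. Each simulation run takes
a stratified without-replacement sample of $n/2$ per class, trains quadratic
discriminant analysis (QDA), and measures the true conditional error $e_i$
as the misclassification proportion on the $10{,}000-n$ unsampled members.
This makes the estimand a concrete, exactly computable number at the cost of
a shared finite-population offset of order
$\sqrt{e(1-e)/10^4} \approx 0.005$, which our test tolerances carry
explicitly.

## The six schemes

Retraining budgets are equalized at $B\times n$ fits ($B=50$), except
LOOCV, which is unique and runs once:

| scheme | folds | repetitions $R$ | resample |
|--------|-------|------------------|----------|
| kCVn (LOOCV) | $n$ | 1 | none |
| BCVn | $n$ | $B$ | bootstrap |
| kCVn/2 | $n/2$ | $2B$ | permutation |
| BCVn/2 | $n/2$ | $2B$ | bootstrap |
| kCV10 | 10 | $Bn/10$ | permutation |
| BCV10 | 10 | $Bn/10$ | bootstrap |

Permutation schemes randomly re-partition the original $n$ observations;
folds differ in size by at most one and are *not* class-stratified (the
study's description is a plain random division; a stratified variant is a
configuration switch, off by default). Bootstrap schemes draw a size-$n$
with-replacement sample — unstratified for $p=1$, $n/2$ per class for $p=5$
— and cross-validate entirely inside it, so duplicates of a test point can
and do occur in its training part; that leakage is the mechanism under
study and is deliberately not "fixed". A resample must contain at least 4
($p=1$) or 8 ($p=5$) distinct observations per class for QDA to be stably
trainable; violating draws are rejected and redrawn, with redraw counts
logged (the published account states the constraint but not the remedy;
rejection sampling is the minimal intervention). A resample that still
yields a degenerate fold is likewise redrawn; exhausting the cap (10,000
tries per repetition) raises a typed error rather than silently truncating.

## The decomposition

With $\hat e_{ri}$ the $r$-th repetition estimate in run $i$ and
$\bar e_{Ri}$ their mean,
$$\mathrm{MSE}_i = \tfrac1R\sum_r(\hat e_{ri}-e_i)^2
 = \underbrace{\tfrac1R\sum_r(\hat e_{ri}-\bar e_{Ri})^2}_{\mathrm{VAR}_i}
 + \underbrace{(\bar e_{Ri}-e_i)^2}_{\mathrm{BIAS}_i^2},$$
and over $N$ runs $\overline{\mathrm{MSE}} = \overline{\mathrm{VAR}} +
\mathrm{MSB}$ with $\mathrm{MSB} = \frac1N\sum_i \mathrm{BIAS}_i^2$. The MSB
further splits into spread and mean parts. Two divisor conventions meet
here: the averages use $1/N$, while the reported dispersions SD(MSE),
SD(VAR), SD(BIAS) are sample standard deviations with $1/(N-1)$ — the
printed definitions of the first two are corrupted in the source, and the
$1/(N-1)$ reading is the only one consistent with the third. The identity
the package enforces and tests is therefore
$$\mathrm{MSB} = \tfrac{N-1}{N}\,\mathrm{SD}(\mathrm{BIAS})^2 +
\overline{\mathrm{BIAS}}^2,$$
which also reproduces the published table numerics. Both identities hold to
$10^{-10}$ on every simulation output; they are exact algebra, so any
violation would indicate an accumulation bug, not noise.

## QDA choices

QDA is implemented from scratch (it is part of what is under study): class
means and covariances from the training part, discriminant
$\delta_c(x) = -\frac12\log\lvert\Sigma_c\rvert - \frac12 (x-\mu_c)^\top
\Sigma_c^{-1}(x-\mu_c) + \log\pi_c$, exact ties to class 1 (deterministic;
measure-zero for continuous data). Priors are fixed at $(0.5, 0.5)$
everywhere, including inside bootstrap resamples with unbalanced class
counts: the populations and samples are balanced by design and re-estimated
priors would conflate prior noise with the resampling effects being
measured. The covariance divisor is unbiased $1/(m-1)$ by default, with a
$1/m$ switch; the original study does not state its choice, and at the
study's $n$ the difference is far inside Monte Carlo noise. Training with a
non-positive-definite class covariance raises a typed degenerate-training
condition — no ridge term is added, staying faithful to the
distinct-observation remedy. The hot loop (one QDA fit per fold, millions of
fits per study) is C++ via RcppArmadillo, using fold-subtracted class
moments so a LOOCV fold costs $O(p^2)$; all randomness flows through R's
RNG, so results are reproducible from a single seed.

## Seeds and problem sizes

One master seed spawns child seeds per (run, scheme) through an exact
integer-mixing map (`derive_seed()`), so any single cell of a results table
can be regenerated in isolation. The package's reference checks run the
twenty-configuration sweep at $N = 200$ runs per cell and the single-cell
anchors at the published $N = 1000$; tolerances for reproducing printed
values scale as $3\,\mathrm{SD}/\sqrt N$ with the corresponding dispersion
column, plus the super-population term for mean true errors. Sign-pattern
checks (bootstrap CV negatively biased beyond the $0.25$
$|\overline{\mathrm{BIAS}}|/\mathrm{SD}(\mathrm{BIAS})$ threshold at $p=5$,
permutation CV below it) are made statistically at $3$ standard errors of
the ratio ($\approx 3/\sqrt N$): at $N=200$ a hard cut at $0.25$ would test
Monte Carlo noise rather than the estimators.

## What the generator does and does not emulate

The synthetic design covers exactly the published study conditions:
independent Gaussian features, balanced classes, $p \in \{1,5\}$,
$\Delta \in \{1,3\}$, $n \in \{20,50,100\}$ ($p=1$) or $\{50,100\}$
($p=5$). It does not emulate correlated features (positive correlation
would shrink the effective Mahalanobis separation), non-Gaussian or
heavy-tailed data, unbalanced classes, or $p > n$ regimes — passing tests
say nothing about those. The dataset runner (`run_dataset_study()`)
transfers the protocol to any finite labeled table, treating the unsampled
remainder as the holdout and selecting features by Welch $t$-statistic with
Benjamini–Hochberg adjustment inside each subsample (selection before
subsampling is a known optimism source; a `global_selection` switch exposes
it deliberately). The gene-expression dataset the original comparison used
is an external download and is not bundled; the bundled demonstration table
is synthetic and labelled as such.

## Repository shape

The package is organised as an analysis workflow: the numbered scripts
under `analysis/` are thin drivers (simulate the sweep, draw the
figure-style diagnostics, run a dataset example) over the functions in
`R/`, where every computation lives and is unit-tested. The scripts plus
the exported functions are the interface; there is no separate command-line
wrapper.

## Known limitations

- The unequal-covariance Bayes error has no closed form here; `bayes_error()`
  falls back to a seeded $10^6$-point Monte Carlo evaluation of the optimal
  quadratic rule (standard error about $5\times 10^{-4}$).
- `per_partition_conditional_errors()` — a separate true error per
  fold-trained model, the diagnostic that isolates how much SD(BIAS) is
  inflated by treating a moving target as fixed — is exact but $O(NRk)$
  holdout evaluations, intended for small exploratory studies.
- Aggregation uses R's built-in summation on length-$N$ vectors
  ($N \le 10^3$ here), where double-precision round-off is orders of
  magnitude below the $10^{-10}$ identity tolerance; no compensated
  summation is needed at these sizes.
```{r session}
sessionInfo()
```
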