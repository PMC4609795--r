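---
title: "Benchmarking feature selection on negative binomial count data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking feature selection on negative binomial count data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nbfsbench)
```

## The problem

Sequencing-based case/control studies (bulk or small-RNA) produce integer
count matrices that are overdispersed relative to Poisson and typically have
far more features than samples. Methods that select the disease-associated
features fall into three families: hypothesis tests built on the negative
binomial (NB) model, distribution-free tests, and machine-learning selectors.
`nbfsbench` provides a controlled simulation bench on which these families
can be compared on equal terms — with the NB testing machinery implemented
from scratch inside the package so that every modelling choice is explicit —
plus a repeated cross-validation harness for downstream classification and an
Apriori miner for feature sets that recur across cohorts.

## The generator

Counts follow an NB distribution parameterized by its mean $\mu$ and
dispersion $\phi$,

$$\mathrm{Var}(X) = \mu + \phi\,\mu^2,$$

so $\phi = 0$ degenerates to Poisson and larger $\phi$ inflates the counts.
This is the convention of the NB testing literature and matches the intuition
that overdispersion grows with the dispersion parameter.

A scenario (`scenario_config()`) fixes 20 case and 20 control samples and
500 features. A leading block of features is *significant*: NB($\mu_c$,
$\phi_c$) in cases versus NB(5, 1) in controls, with all effects upward
(cases have larger means). The remaining features are noise, NB(5, 1) in
both groups. The signal-to-noise ratio `s2n` is the ratio of significant to
insignificant features; read literally, `n_sig = round(500 * s2n / (1 +
s2n))` (45 at `s2n = 0.1`), with a `"proportion"` switch for the
`round(500 * s2n)` reading (50). All benchmark quantities reported here are
insensitive to that choice. The significant block sits at the top of the
matrix with the truth mask carried alongside; no shuffling is needed because
every selector is order-agnostic.

The grid of `scenario_grid()` varies one axis at a time around the baseline
($\mu_c = 20$, $\phi_c = 1$, `s2n = 0.1`):

| axis | scenarios | values |
|------|-----------|--------|
| s2n | A1–A5 | 0.01, 0.05, 0.1, 0.15, 0.20 |
| case mean $\mu_c$ | B1–B5 | 10, 15, 20, 25, 30 |
| case dispersion $\phi_c$ | C1–C5 | 0.125, 0.5, 1, 2, 8 |

A3, B3 and C3 coincide with the baseline. Each replication derives its RNG
stream from `(seed, rep_index)`, so replications are bit-reproducible and
independent of evaluation order or worker count.

What the generator deliberately omits: library-size variation, batch
effects, feature–feature correlation and zero inflation. Passing benchmarks
on these data therefore demonstrates behaviour under the clean NB model
only; on real data, correlated features and technical covariates can change
the ranking of methods.

## The NB testing machinery

All three sequencing-style tests share a common core, implemented in the
package (no external differential-expression package is called anywhere).

**Size factors.** Median-of-ratios: each sample's factor is the median over
features of its count divided by the feature's geometric mean, rescaled to
geometric mean one. At the simulation's count depth (mean 5) almost every
feature contains a zero, so the textbook estimator would be left with a
handful of reference features and simply echo their noise; the implementation
therefore requires a minimally informative reference set (roughly ten
all-positive features) and otherwise falls back, with a warning, to a
pseudocount-smoothed median-of-ratios over all features (counts + 0.5). Even
then, factors carry an irreducible sampling sd of about 6% on the log scale
at ~2500 counts per sample — a property of the data, not the estimator; a
trimmed-mean variant was evaluated and performed no better. Because the
generator has no true library variation, factors hover near 1 and the
rounding of normalized counts is nearly a no-op.

**Common and tagwise dispersion.** Conditioning each feature's group counts
on their group total removes the mean and leaves a likelihood in $\phi$
alone (the conditional maximum likelihood idea). The common estimate
maximizes the sum over features by Brent search on $\log\phi \in [10^{-6},
10^2]$ (relative tolerance $10^{-4}$; boundary hits are returned as 0 or the
cap with a warning). Tagwise estimates maximize the weighted conditional
log-likelihood $WL_g(\phi) = l_g(\phi) + \alpha\,\bar l(\phi)$ on a
161-point log-spaced grid with parabolic refinement; $\alpha$ interpolates
between fully individual ($\alpha = 0$) and fully common estimates. The
default $\alpha = 20/(n-2)$ makes the common component worth twenty prior
observations per feature — a fixed, documented constant; the weighting
constant is not prescribed by the benchmark design, and power at the
scenarios reported below is insensitive to it.

**Pooled mean–variance regression.** The alternative dispersion strategy
computes, per feature, the pooled mean and the pooled within-group variance
of normalized counts, subtracts the shot-noise term ($w = v - \mu$), and
fits a robust loess (degree 1, symmetric family, span 0.3) of raw variance
on mean across all features. Dispersions derive as $\phi_g = \max(0,
f(\mu_g))/\mu_g^2$. With a single replicate per group the variance is
computed blind across all samples, which conservatively absorbs the group
difference — this is what lets the test run at one sample per group.

**The conditional exact test.** Under the null, the case-group sum $A$ of
$n_1$ i.i.d. NB($\mu$, $\phi$) counts is NB($n_1\mu$, size $n_1/\phi$), and
$P(A = a \mid A + B = T) \propto P(A = a)\,P(B = T - a)$. The two-sided
p-value sums the conditional probabilities of all splits no more likely than
the observed one. For $T > 10^4$ the enumeration is restricted to ±12
conditional standard deviations around the conditional mean; the excluded
mass is below $10^{-12}$ and the windowed result matches full enumeration to
$10^{-10}$ in the tests. The package tests pin this implementation against a
brute-force oracle that builds the group-sum distributions by explicit
convolution of per-sample pmfs.

**The empirical-Bayes posterior.** A two-model comparison: M0 shares one NB
mean/dispersion across all samples, M1 gives each group its own mean.
Parameter priors are formed empirically from 100 bootstrap draws of
feature-wise moment estimates; marginal likelihoods average the NB
likelihood over those draws; and the DE-model proportion is estimated by
iterating posterior re-weighting to convergence (tolerance $10^{-6}$, warn
after 500 iterations). The reported p-value is one minus the posterior —
which makes it a model-averaged quantity, not a frequentist tail
probability; it is deliberately conservative under the null.

## The other selectors

* **Rank sum** — exact enumeration of the permutation distribution (ties via
  midranks) for group sizes up to 8; the tie-corrected,
  continuity-corrected normal approximation otherwise. The large-sample
  path reproduces the standard two-sided approximation to $10^{-10}$.
* **Lasso** — $\ell_1$-penalized logistic regression on
  $\log_2(\text{count}+1)$, standardized; penalty by 10-fold CV at the
  deviance minimum (one-standard-error rule available as a switch); selected
  = nonzero coefficients. Penalized regression on raw counts would be
  scale-pathological, hence the transform.
* **PSODT** — binary particle-swarm search over feature-inclusion masks,
  fitness = decision-tree accuracy under internal stratified 3-fold CV,
  inertia 0.72 and cognitive/social coefficients 1.49 with a sigmoid
  transfer (standard binary-PSO constants). Per iteration, every feature in
  the current position of a particle whose personal best equals the global
  best gains a score point. "Personal best equals global best" is read as
  equality of fitness values and credited per particle per iteration — one
  of several defensible readings; the selection rule (score positive in at
  least half the restarts) is likewise a documented choice, and no headline
  quantity depends on either.
* **Random forest** — 500 trees, `mtry = floor(sqrt(p))`, permutation
  importance; selected = importance z-score above 2. Using *all* variables
  per split would remove the randomness that gives the forest its variance
  reduction, so the square-root default is used.

## Evaluation harness

`run_replications()` simulates, applies each selector, and averages the
confusion counts over replications; sensitivity, specificity, type-I error
and power are formed from the mean counts (with fixed class sizes this
equals the mean of per-replication rates). P-value selectors are evaluated
at the nominal 0.05 level and at the Bonferroni level 0.05 divided by the
number of features tested (500 in simulation). Method failures within a
replication are logged, warned about and excluded from that method's
average. Per-replication and per-method RNG streams are derived from the
root seed, so results are identical for any worker count.

## Classification stage

`repeated_cv()` runs repeated stratified 5-fold cross-validation with
feature selection inside the training folds only — the no-leakage contract
is directly testable through `cv_select()`, which ignores everything outside
the training indices. Stratification is used because the matched designs
this emulates have balanced classes. Classifier inputs are
$\log_2(\text{count}+1)$, standardized with training-fold statistics.
Logistic regression uses an iteration-capped IRLS with a $10^{-8}$ ridge
jitter so it stays numerically solvable when features approach the sample
count — it degrades rather than errors, which is the behaviour under study.
The SVM is an RBF-kernel soft-margin classifier with $\gamma = 3$ and cost 1;
a regression-style $\varepsilon$ is accepted but ignored with a warning
since it has no role in classification. PPV/NPV threshold predictions at
probability 0.5 (decision value 0).

Two properties of this stage are worth stating because they surprise at
first sight. First, cross-validated AUC under a *single* label permutation
is not 0.5: in-fold selection finds chance structure that persists into the
held-out folds of that same permutation, spreading per-permutation AUC by
roughly ±0.13 at n = 80. Chance level is recovered in expectation over
permutations, and that is what the tests assert. Second, logistic regression
slides monotonically toward chance as the number of selected features
approaches the training-fold size — reproduced in the tests as a monotone
property rather than a fixed number.

## Itemset mining

Cohorts are transactions and eligible deregulated features are items.
Eligibility is three-staged: Bonferroni significance in at least one
p-value method, selection at least 80 times out of 100 CV repeats in at
least one algorithm, and flagging (frequency at least half the repeats) by
at least three algorithms; the 100-repeat base is inferred from the
cross-validation design. The Apriori miner generates itemsets level-wise
with the downward-closure prune; rules report support, confidence and lift
with defaults of 0.5 for both thresholds. With six cohorts, a rule whose
antecedent occurs exactly in the three transactions containing the
consequent has confidence 1 and lift 2 — the worked example in the
acceptance script. The miner is pinned against exhaustive subset
enumeration for small universes.

## Numerical choices and degenerate inputs

* Dispersion search range $[10^{-6}, 10^2]$; flat profiles near zero are
  reported as 0 (underdispersed boundary) with a warning.
* Exact test: "no more likely" uses a relative tolerance of $10^{-7}$ so
  equal-probability splits are included regardless of rounding; $T = 0$
  returns p = 1.
* Constant features: rank-sum p = 1; constant-mean matrices fall back to a
  constant raw-variance fit with a warning; all-zero matrices are an error
  for size factors and the low-expression filter.
* Real-data loading filters features whose total count is strictly below 10
  (a row summing to exactly 10 is kept), records removals in a provenance
  log, and is idempotent.

## Problem sizes used in the shipped checks

The replication budget defaults to 1000. The package's own acceptance
checks use 300 replications for the rank-sum scenarios and 200 for the NB
exact-test scenario — at these budgets the Monte-Carlo standard error of a
sensitivity is below 0.01, comfortably inside the comparison bands — and
100-replication runs for monotonicity sweeps. Property suites run at small
problem sizes where brute-force oracles are exact.

## Known limitations

* The NB implementations target methodological fidelity, not numerical
  replication of any released differential-expression package (no quantile
  adjustment, shrinkage priors or Cox–Reid correction).
* The empirical-Bayes method's detection threshold depends on the bootstrap
  prior; its headline numbers are reproduced qualitatively (conservative
  null, high power at large effects), not cell-by-cell.
* Real-data classification tables depend on external cohorts and are out of
  scope; the classification harness is exercised on synthetic data only.
* The generator's independence assumptions mean specificity estimates here
  are optimistic relative to correlated real count data.
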