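# nbfsbench

Simulation benchmark of feature-selection and classification algorithms for
negative binomial (NB) sequencing-style count data.

Case/control count studies (e.g. miRNA sequencing) must find the handful of
truly deregulated features among hundreds, from overdispersed integer counts
and small samples. `nbfsbench` rebuilds that comparison as a tested, reusable
pipeline:

* **Generator** — case/control NB count matrices, `Var(X) = μ + φμ²`, over a
  15-scenario grid varying the signal-to-noise ratio (A1–A5), the case-group
  mean of significant features (B1–B5) and their dispersion (C1–C5) around a
  baseline of 20 + 20 samples, 500 features, control/noise NB(5, 1).
* **NB testing machinery, from scratch** — median-of-ratios size factors;
  common and tagwise dispersion by (weighted) conditional maximum
  likelihood; a pooled mean–variance local regression; the conditional
  exact test on group sums (`P(A = a | A + B = T)`, two-sided by the sum of
  less-likely outcomes); and a two-model empirical-Bayes posterior of
  differential expression. No external differential-expression package is
  called.
* **Selectors behind one interface** — the three NB pipelines plus the
  Wilcoxon rank-sum test (exact for small groups, tie-corrected normal
  approximation otherwise), cross-validated lasso-logistic, a binary
  particle-swarm/decision-tree wrapper (PSODT), and random-forest
  permutation importance.
* **Evaluation harness** — type-I error, power, sensitivity and specificity
  (`Sens = TP/(TP+FN)`, `Spec = TN/(TN+FP)` on counts averaged over
  replications) at the nominal 0.05 and Bonferroni (0.05/500) levels.
* **Classification stage** — repeated stratified 5-fold CV with feature
  selection inside the training folds; logistic / RBF-SVM (γ = 3) /
  random-forest classifiers; AUC, PPV, NPV.
* **Itemset mining** — Apriori over per-cohort deregulated-feature sets with
  support/confidence/lift (defaults 0.5/0.5) and the three-stage
  eligibility rule (Bonferroni + selected ≥ 80/100 CV repeats in one
  algorithm + flagged by ≥ 3 algorithms).

## Worked example

Rank-sum selection under the high-dispersion scenario C5 (case features
NB(20, 8) versus control NB(5, 1)), 100 replications:

```r
library(nbfsbench)

cfg <- scenario_grid(seed = 42)[["C5"]]
cfg
#> scenario 'C5': n=20/20, 500 features, s2n=0.1 (45 significant)
#>   significant: case NB(mu=20, phi=8) vs control NB(mu=5, phi=1)
#>   noise:       NB(mu=5, phi=1) in both groups

res <- run_replications(cfg, "ranksum", n_reps = 100, seed = 42)
res[, c("level", "sensitivity", "specificity", "type1")]
#>        level sensitivity specificity    type1
#>      nominal     0.22711       0.952 0.048220
#>   bonferroni     0.00333       1.000 0.000022
```

The dispersion inflation cripples the rank-sum test: only ~23% of the truly
significant features reach p < 0.05 (versus ~100% at case dispersion 0.125),
and essentially none survive the Bonferroni threshold — while the type-I
error stays at its nominal 5%. A single replication can be inspected
directly:

```r
d <- simulate_dataset(cfg, 1)
d
#> labeled_count_matrix: 500 features x 40 samples (20 case / 20 control), 45 significant
edger_like_test(d)
#> de_result [edger]: 500 features, 47 with p < 0.05
```

A thin command-line wrapper covers the same ground
(`Rscript inst/cli/nbfsbench.R benchmark --scenario C5 --methods ranksum
--reps 100 --seed 42 --out c5.tsv`), with `simulate`, `classify` and
`itemsets` subcommands.

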