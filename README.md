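# crisprimerf

Predicting bacterial CRISPRi guide efficiency from pooled depletion screens
with a mixed-effect random forest.

## The problem

In a pooled CRISPRi essentiality screen, every guide's depletion (log2
fold-change of its abundance over growth, logFC) mixes two signals: the
fitness cost of silencing the targeted gene and the efficiency of silencing
itself. Gene-level effects — expression, operon context, polar effects on
downstream essential genes — dominate the measurement, so a model trained
directly on logFC learns gene biology rather than guide design rules. This
package is for computational biologists who want to train a guide-efficiency
predictor from such indirect measurements, fuse several screens, and obtain
interpretable design rules.

## The model

For observation *i* of a guide targeting gene (cluster) *c(i)*:

```
y_i = f(X_i) + Z_i b_c(i) + eps_i,    b_c ~ N(0, D),  eps_i ~ N(0, sigma^2)
```

* `f` — a random forest over 129 guide features (fixed effects): one-hot
  30-nt target context (120), four hybridization/folding energies,
  distance to start codon (absolute and relative), distance to the
  transcription-unit start, longest homopolymer, first-gene-in-operon
  indicator;
* `Z b_c` — per-gene linear random effects over an intercept plus 9
  standardized gene/dataset features (expression min/max, gene GC, length,
  downstream (essential) gene counts, codon adaptation index, two dataset
  indicators). The random intercept absorbs each gene's depletion scale, so
  multiple screens fuse without explicit normalization.

`merf()` fits the model by expectation–maximization (seeded forest refit,
BLUP E-step, variance-component M-step, generalized log-likelihood
stopping). `predict(fit, X, type = "fixed")` scores guides independently of
the targeted gene — the guide-efficiency score. Evaluation is gene-wise:
held-out genes, per-gene Spearman correlation, top-20% enrichment, and the
PPV of the top-k predicted guides within N-fold of each gene's best guide.
`attribute()` provides exact TreeSHAP-style feature attributions with
interaction and distance-window analyses. A synthetic screen generator with
a known `logFC = gene effect + guide effect + noise` decomposition makes
the whole pipeline testable end to end.

## Worked example

Simulate a small screen (60 genes x 10 guides, gene-effect SD 2.0,
guide-effect SD 1.0, noise SD 0.5 log2 units), fit, and evaluate on
held-out genes:

```r
library(crisprimerf)
cfg <- sim_preset("small")          # 60 genes x 10 guides
st  <- simulate_study(cfg)          # genome -> guides -> screen -> features
fit <- merf(st$X, st$Z, st$cluster, st$y,
            hp = merf_hyperparams(n_estimators = 200),
            max_iter = 12, seed = 7)
fit
#> Mixed-effect random forest
#>   observations: 600  clusters: 60  q: 10
#>   fixed effect: ranger (200 trees)
#>   sigma2: 0.3881  iterations: 11  converged: TRUE

folds <- split_genewise(st$cluster, k = 5, seed = 7)
test  <- st$cluster %in% folds[[1]]$held_out_units
cvfit <- merf(st$X[!test, ], st$Z[!test, ], st$cluster[!test], st$y[!test],
              hp = merf_hyperparams(n_estimators = 200),
              max_iter = 12, seed = 7)
score <- predict(cvfit, st$X[test, ], type = "fixed")

per_gene_spearman(score, st$y[test], st$cluster[test])$median
#> [1] 0.6484848
enrichment_top20(score, st$y[test], st$cluster[test])
#> [1] 50
ppv_topk(score, st$y[test], st$cluster[test], k = 3, fold_n = 2)
#> [1] 0.3888889
cor(cluster_effects(fit, st$Z, st$cluster),
    st$truth$gene_effects[fit$clusters])
#> [1] 0.9744814
```

Reading the numbers: on genes never seen in training, the fixed-effect
score ranks guides within a gene at a median Spearman correlation of 0.65
against measured depletion; half of the predicted top-20% guides are truly
in the top 20% (random guessing gives 20%); and 39% of the top-3 picks per
gene deplete within two-fold of that gene's best guide. On the training
genes, the model's gene-level random effects recover the simulated true
gene effects at r = 0.97 — the separation of gene from guide signal that
the model exists to provide.

A thin command-line workflow over the same functions lives in
`inst/scripts/crispri_merf.R` (`simulate`, `design`, `train`, `predict`,
`evaluate`), each command writing a manifest with option echo and input
checksums for reproducibility.

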