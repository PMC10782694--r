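---
title: "Separating guide efficiency from gene effects in CRISPRi depletion screens"
author: "crisprimerf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating guide efficiency from gene effects in CRISPRi depletion screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Pooled CRISPRi screens measure, for each guide RNA, the change in abundance
(log2 fold-change, logFC) of the cells carrying it over growth. For guides
targeting genes whose silencing is costly, this depletion mixes two signals:
the fitness cost of knocking the gene down, and how efficiently the guide
silences at all. Only the second is useful when designing guides for a new
target, yet the first dominates the measurement — expression level, operon
context and downstream essential genes (polar effects) move whole genes up
and down the depletion scale. A model trained naively on logFC therefore
learns mostly gene biology, not guide design rules.

`crisprimerf` separates the two with a mixed-effect random forest. For
observation $i$ of guide $g(i)$ targeting gene (cluster) $c(i)$:

$$y_i = f(X_i) + Z_i b_{c(i)} + \varepsilon_i, \qquad
  b_c \sim N(0, D), \quad \varepsilon_i \sim N(0, \sigma^2)$$

* $f$ is a random forest over the 129 guide-level features $X$ (fixed
  effects): the one-hot 30-nt target context, four hybridization/folding
  energies, distances to the start codon and to the transcription-unit (TU)
  start, the longest homopolymer run, and a first-gene-in-operon indicator.
* $Z$ holds an intercept plus 9 standardized gene/dataset features (min and
  max expression over growth, gene GC, gene length, downstream gene and
  downstream essential gene counts, codon adaptation index, and two
  treatment-coded dataset indicators); $b_c$ are per-gene random
  coefficients with covariance $D$.
* The random intercept absorbs each gene's overall depletion scale. This is
  what lets several screens be fused **without** explicit renormalization:
  a guide assayed in two screens simply contributes two observations in the
  same gene cluster, and scale differences between screens load onto the
  random effects through the dataset indicators.

Prediction for new guides uses $f$ alone (`predict(fit, X, type =
"fixed")`): a score independent of the targeted gene's identity, which is
exactly the quantity needed for guide ranking within a gene.

## Fitting: EM with a seeded forest

`merf()` alternates, for at most `max_iter` iterations:

1. subtract the current random effects, $y^*_i = y_i - Z_i b_{c(i)}$, and
   refit the forest $f$ on $(X, y^*)$ **with the same seed each time**, so
   the fixed point is deterministic given (data, hyperparameters, seed);
2. E-step: $b_c = D Z_c^\top V_c^{-1}(y_c - f(X_c))$ with
   $V_c = Z_c D Z_c^\top + \sigma^2 I$ (the BLUPs, available directly as
   `estep_blups()`);
3. M-step updates of $\sigma^2$ and $D$ from the within-cluster residuals
   and BLUP posteriors.

Convergence is declared when the relative change of the generalized
log-likelihood criterion (GLL: residual, random-effect, $\log|D|$ and
$\log\sigma^2$ terms) drops below `tol` (default `1e-3`, cap 50
iterations). Initialization is $b = 0$, $D = I$, $\sigma^2 = 1$.

Two numerical details are worth knowing:

* **GLL drift.** When some directions of $D$ carry no real variance (here,
  gene features are constant within a cluster, so only the total
  $Z_c b_c$ is identified per cluster), EM drives the corresponding
  eigenvalues geometrically toward zero and the $\log|D|$ term drifts
  slowly downward. The relative-change rule still terminates (the drift is
  a vanishing fraction of the criterion), but on hard cases the fit can use
  all 50 iterations. The predictive quantities — fixed-effect scores and
  the per-gene totals `cluster_effects()` — stabilize within roughly ten
  iterations; the tests pin this behaviour.
* **Identifiability of the BLUPs.** Because $Z$ rows are identical within a
  cluster, individual coefficients in $b_c$ (e.g. "the intercept") are not
  separately identified; `cluster_effects()` returns the identified
  per-gene total $z_c^\top b_c$, which is the model's gene-effect estimate
  and what parameter-recovery checks compare against simulated truth.
* Near-singular $D$ gets a logged `1e-8` ridge inside the GLL only; the
  M-step itself projects $D$ back onto the PSD cone when round-off pushes
  an eigenvalue slightly negative.

The forest backend is `ranger` (single-threaded, seeded). Hyperparameters
(`merf_hyperparams()`) default to mid-range values of the supported search
space — 500 trees, depth 15, feature fraction 0.3, minimum leaf 5,
bootstrap — and `tune_hyperparameters()` runs a seeded random search over
that space against any objective (the natural one: median per-gene Spearman
under gene-wise cross-validation). One mapping note: the backend exposes a
single node-size control, so `min_samples_split` is validated and carried
but node growth is governed by `min_samples_leaf`.

## Feature engineering choices

* **Strand convention.** CRISPRi within an open reading frame requires the
  guide to anneal to the coding (non-template) strand. `enumerate_guides()`
  therefore scans the mRNA-sense sequence for `CC` dinucleotides (the
  reverse complement of the `NGG` PAM in protospacer orientation); the
  protospacer is the following 20-mer's reverse complement, and the
  reported 30-nt context (4 nt upstream, 20-nt target, PAM, 3 nt
  downstream) is given in protospacer orientation.
* **Distance anchor.** Distances are 0-based offsets of the protospacer's
  PAM-distal end (G1) from the first base of the start codon, in
  mRNA-sense coordinates. Any consistent anchor would shift all distances
  by a constant below the guide length; the model only consumes relative
  structure.
* **Filters.** GC bounds on the 20-nt spacer are inclusive at 0.30 and
  0.85; the forbidden-motif screen (default BbsI, `GAAGAC`/`GTCTTC`,
  checked on both strands) removes guides that would break Golden-Gate
  library cloning.
* **Thermodynamics.** Four minimum free energies: guide self-folding,
  guide homodimer, guide:target-DNA hybrid, and the hybrid of the 8-nt
  PAM-proximal seed (G13–G20). The engine is injectable: the ViennaRNA
  programs (`thermo_engine_vienna()`, using `RNAfold`/`RNAduplex`; the
  RNA:DNA hybrid is approximated with RNA parameters), a built-in
  nearest-neighbour model (`thermo_engine_nn()`; dinucleotide stacking for
  perfectly complementary hybrid duplexes, best ungapped antiparallel
  duplex for the homodimer, best single hairpin with a flat loop penalty
  for self-folding), and a constant stub for tests. The built-in model is
  the default in the simulation pipeline: it is deterministic, fast, and
  preserves the orderings that matter (shorter duplexes never beat longer
  ones; structure-free sequences score 0).
* **Expression summaries.** Per-gene expression minima and maxima are taken
  over the ODs up to the growth stage at which a screen was collected
  (`od_cap`, per dataset); the codon adaptation index is the geometric mean
  of relative codon adaptiveness, excluding stop codons and
  single-codon amino acids — a sequence-only expression proxy for organisms
  without transcriptomes.
* **Dataset coding.** Treatment coding with the first dataset as reference
  keeps the random block at exactly 9 columns for three datasets.
* The random block is standardized to zero mean and unit *population*
  variance per column (constant columns map to zero), so $D$ is estimated
  on comparable scales.

## Cross-screen fusion

For models that need a single response scale (baselines, diagnostics), the
package implements the scaling route: screens sharing a library are
averaged (`average_shared_library()`); an independent screen is mapped onto
that scale by OLS on overlapping guides (`fit_scaling()`), after which the
overlap is dropped from the mapped screen to avoid double counting.
Activity scores — scaled logFC minus the per-gene median (pooled across
datasets; configurable) — are produced after dropping genes with fewer than
5 guides in a dataset, whose medians would be unstable. Within
cross-validation, scaling must be refit inside each training fold; the CV
harness operates on raw logFC for the mixed model, where no scaling exists
to leak. The even-count median uses midpoint interpolation.

## Evaluation

True guide efficiency is never observed, so models are scored **within
genes** on held-out genes (`split_genewise()`: genes shuffled by seed and
dealt into near-equal folds; every guide of a held-out gene is held out):

* `per_gene_spearman()` — rank agreement per gene (average-rank ties),
  summarized by the median over genes; genes with under two usable guides
  or constant vectors are skipped with a notice.
* `enrichment_top20()` — overlap between the top `ceil(0.2 n)` most
  depleted and top-predicted guides per gene, pooled (per-gene averaging
  available); calibrates to ~20% under random predictions.
* `ppv_topk()` — pick the `k` best-predicted guides per gene; a pick is a
  true positive when its logFC is within N-fold of the gene's most
  depleted guide, i.e. `obs <= min(obs) + log2(N)` ("within N-fold" is
  interpreted on the fold-change scale since logFC is log2). TP/FP pool
  across genes.
* `hamming_diagnostics()` — min/median pairwise Hamming distance between
  train and test guide contexts, to flag near-duplicate leakage.

Ties in observed logFC are broken by position for determinism.

## Attribution

`attribute()` explains fixed-effect predictions with additive per-feature
contributions. The exact backend is a from-scratch implementation of the
path-dependent TreeSHAP recursion over the extracted ranger trees, with
node covers taken from routing the training data; it is deterministic and
satisfies local accuracy (base value + row sum = prediction) to
floating-point error, verified against exhaustive Shapley enumeration on
small trees. A model-agnostic permutation backend (seeded permutation
orders against a background sample) is available for any learner; it also
satisfies local accuracy exactly because each permutation's contributions
telescope.

On top of the attributions: `mean_abs_importance()` (global ranking),
`interaction_combination_table()` — the median observed vs expected
attribution across the four presence strata of a feature pair (-/-, +/-,
-/+, +/+), whose +/+ deviation flags non-additive interactions — and
`rank_interaction_pairs()`, which screens pairs by that deviation. This
median-combination screen replaces pairwise SHAP-interaction matrices: it
needs only single-feature attributions, scales to all one-hot pairs, and
tests the same additivity hypothesis. "Present" for one-hot features means
the indicator equals 1; continuous features require a user threshold.
`distance_effect_profile()` contrasts the distance feature's attribution
inside vs beyond a 60-nt window from the start codon, optionally split by
the first-gene indicator.

## The simulator, and what passing its tests does (not) show

`simulate_genome()` / `simulate_screen()` / `simulate_counts()` generate
screens with a known decomposition `logFC = gene effect + guide effect +
noise` (exact by construction):

* genes of uniform base composition (600 nt) laid head-to-tail in
  transcription units (2 genes/TU, 60-nt spacers), log-normal expression
  over 10 ODs, half the genes labelled essential;
* gene effect: $-|\kappa\, z(\log \text{expr})| - 0.3\,n_{\text{downstream
  essential}} + N(0, \sigma_g^2)$ — higher expression and polar effects on
  essential genes mean stronger depletion;
* guide effect: per-position sequence weights over the 30-nt context
  (defaults qualitatively mirror the screen-derived preferences: C
  favourable at the variable PAM position and directly after the PAM, G
  unfavourable there, A/G unfavourable at G20, seed-region contributions),
  minus a 1.5 log2 bonus within 60 nt of the start codon, plus
  $N(0, \sigma_u^2)$;
* counts: negative-binomial (dispersion 0.01) around `library_size /
  n_guides`, output means scaled by $2^{\text{logFC}}$, two replicates
  (second 1.15× deeper), 50 non-targeting controls at logFC 0.

The `"default"` preset (300 genes × 10 guides; SDs 2.0 / 1.0 / 0.5 log2
units; seed 7) makes gene-level confounding twice as large as guide-level
signal, the regime the model exists for. The sequence weights were chosen
once so that the feature-driven share of guide variance (~2–3 log2²) is
comparable to the unexplainable share (1.0) — a regime where a forest can
demonstrably recover the ranking (Spearman vs true guide effects ≳ 0.9 in
training, ~0.7 on held-out genes) without making the task trivial.

What the simulator does **not** emulate: realistic genomic sequence
composition and motif biases, guide-specific count dispersion, PCR and
sequencing error, off-target effects, time-course kinetics, or non-additive
gene-guide interactions. Passing the recovery tests therefore shows the
estimator separates additive gene and guide signals under realistic noise —
it does not certify performance on real screens, which is why the package
keeps the external-data reproductions (guide library counts, training-table
sizes, published correlations) clearly apart from the synthetic acceptance
checks.

Test and acceptance problem sizes (300 × 10 for recovery, a 60-gene variant
for count round trips, 200 trees, EM capped at 12–50 iterations) were
chosen as the smallest sizes at which the recovery statistics are stable
across seeds.

## Known limitations

* The count-to-logFC estimator is a normalized pseudo-counted log-ratio
  with replicate averaging, not a count GLM; it produces point estimates
  only (no significance testing), which is all the downstream modelling
  consumes. The pseudo-count (0.5) is applied on the count scale.
* TMM factors are computed on the non-targeting subset but against
  full-column library sizes; with controls a small fraction of the library
  this matches the intended anchoring, and the per-sample factor of a
  globally shifted sample is recovered up to that fraction.
* The ViennaRNA hybrid energy uses RNA parameters (no RNA:DNA parameter
  set ships with the CLI tools); rankings, not absolute energies, are what
  the model consumes.
* Exact TreeSHAP cost grows with tree depth and leaf count; for deep
  production forests, attribute a subsample or use a compact
  explanation forest, as the acceptance script does.
* Random-effect prediction for clusters unseen in training falls back to
  the fixed effect (random effect 0), with a notice.
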