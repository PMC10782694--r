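# Cross-validation splitters and the screen-derived evaluation metrics.
# Because the true efficiency of a guide is never observed directly, models
# are scored within genes: folds hold out whole genes, and metrics compare
# predicted and measured depletion ranks among the guides of each gene.

#' Gene-wise cross-validation folds
#'
#' Shuffles the unique gene ids with the given seed and deals them into `k`
#' near-equal folds; every guide of a held-out gene is held out, so no
#' sequence information about a test gene leaks into training.
#'
#' @param gene_ids vector of gene ids (one per observation or unique)
#' @param k number of folds
#' @param seed RNG seed
#' @return list of `fold_spec` lists: `fold_id`, `held_out_units`, `mode`
#' @export
split_genewise <- function(gene_ids, k = 10L, seed = 1L) {
  units <- unique(as.character(gene_ids))
  make_folds(units, k, seed, mode = "gene_wise")
}

#' Guide-wise cross-validation folds (split on unique guide sequences)
#' @inheritParams split_genewise
#' @param guide_seqs guide sequences or ids
#' @export
split_guidewise <- function(guide_seqs, k = 10L, seed = 1L) {
  units <- unique(as.character(guide_seqs))
  make_folds(units, k, seed, mode = "guide_wise")
}

make_folds <- function(units, k, seed, mode) {
  if (k > length(units))
    stop("k = ", k, " exceeds the number of units (", length(units), ")",
         call. = FALSE)
  restore <- local_rng(seed)
  on.exit(restore())
  shuffled <- sample(units)
  fold_of <- rep_len(seq_len(k), length(units))
  lapply(seq_len(k), function(f)
    structure(list(fold_id = f, held_out_units = shuffled[fold_of == f],
                   mode = mode), class = "fold_spec"))
}

#' Per-gene Spearman correlation between predictions and measurements
#'
#' The primary evaluation of guide-efficiency models: within each gene, the
#' rank agreement (average-rank ties) between predicted and measured
#' depletion; the summary is the median over genes.  Genes with fewer than
#' two guides or a constant vector are skipped with a notice.
#'
#' @param pred,obs numeric vectors
#' @param gene_of gene label per observation
#' @return list with `per_gene` (named vector of rho) and `median`
#' @export
per_gene_spearman <- function(pred, obs, gene_of) {
  stopifnot(length(pred) == length(obs), length(gene_of) == length(pred))
  genes <- split(seq_along(pred), as.character(gene_of))
  rho <- vapply(genes, function(ii) {
    if (length(ii) < 2L) return(NA_real_)
    if (stats::sd(pred[ii]) == 0 || stats::sd(obs[ii]) == 0) return(NA_real_)
    stats::cor(pred[ii], obs[ii], method = "spearman")
  }, numeric(1))
  skipped <- names(rho)[is.na(rho)]
  if (length(skipped))
    message(length(skipped), " gene(s) skipped (too few guides or constant ",
            "values): ", paste(utils::head(skipped, 5), collapse = ", "))
  rho <- rho[!is.na(rho)]
  list(per_gene = rho, median = stats::median(rho))
}

top_frac_idx <- function(v, ii, frac, min_guides) {
  # indices (within ii) of the ceil(frac * n) smallest values, ties broken by
  # position for determinism
  n <- length(ii)
  k <- ceiling(frac * n)
  ii[order(v[ii], seq_len(n))[seq_len(k)]]
}

#' Enrichment of truly efficient guides among predicted-efficient guides
#'
#' Within each gene, the most strongly depleted `top_frac` of guides (most
#' negative measured logFC) are "efficient"; the same fraction of guides
#' with the most negative predictions are "predicted efficient".  Reported
#' is the pooled percentage of predicted-efficient guides that are truly
#' efficient (random predictions give ~ `100 * top_frac` %).
#'
#' @param pred,obs numeric (lower = more depleted/efficient)
#' @param gene_of gene labels
#' @param top_frac fraction treated as efficient
#' @param min_guides genes with fewer guides are skipped
#' @param per_gene if `TRUE` return the mean of per-gene percentages
#'   instead of the pooled percentage
#' @return percentage in \[0, 100\]
#' @export
enrichment_top20 <- function(pred, obs, gene_of, top_frac = 0.2,
                             min_guides = 5L, per_gene = FALSE) {
  genes <- split(seq_along(pred), as.character(gene_of))
  genes <- genes[vapply(genes, length, integer(1)) >= min_guides]
  if (!length(genes)) stop("no gene with >= ", min_guides, " guides",
                           call. = FALSE)
  hit <- vapply(genes, function(ii) {
    eff <- top_frac_idx(obs, ii, top_frac, min_guides)
    sel <- top_frac_idx(pred, ii, top_frac, min_guides)
    c(length(intersect(eff, sel)), length(sel))
  }, numeric(2))
  if (per_gene) return(100 * mean(hit[1, ] / hit[2, ]))
  100 * sum(hit[1, ]) / sum(hit[2, ])
}

#' Positive predictive value of the top-k predicted guides per gene
#'
#' Mimics picking the `k` best-predicted guides to silence each gene: a pick
#' counts as a true positive when its measured logFC lies within `fold_n`
#' fold-change of the gene's most depleted guide, i.e.
#' `obs <= min(obs) + log2(fold_n)`.  TP and FP are pooled over genes.
#'
#' @param pred,obs numeric (lower = more depleted)
#' @param gene_of gene labels
#' @param k picks per gene (genes with fewer guides are skipped)
#' @param fold_n fold-change tolerance (N-fold of the best guide)
#' @return PPV = TP / (TP + FP) in \[0, 1\]
#' @export
ppv_topk <- function(pred, obs, gene_of, k = 3L, fold_n = 2) {
  genes <- split(seq_along(pred), as.character(gene_of))
  genes <- genes[vapply(genes, length, integer(1)) >= k]
  if (!length(genes)) stop("no gene with >= ", k, " guides", call. = FALSE)
  tp <- 0L; total <- 0L
  for (ii in genes) {
    thr <- min(obs[ii]) + log2(fold_n)
    picks <- ii[order(pred[ii], seq_along(ii))[seq_len(k)]]
    tp <- tp + sum(obs[picks] <= thr)
    total <- total + k
  }
  tp / total
}

#' Minimum and median Hamming distance between two sequence sets
#'
#' All pairwise distances between equal-length strings of the training and
#' test sets; a small minimum indicates near-duplicated guide contexts
#' across the split.
#'
#' @param train_contexts,test_contexts character vectors of equal-length
#'   sequences
#' @return list with `min` and `median`
#' @export
hamming_diagnostics <- function(train_contexts, test_contexts) {
  w <- unique(nchar(c(train_contexts, test_contexts)))
  if (length(w) != 1L)
    stop("sequences must all have the same length", call. = FALSE)
  tr <- matrix(unlist(strsplit(train_contexts, "", fixed = TRUE)),
               nrow = length(train_contexts), byrow = TRUE)
  te <- matrix(unlist(strsplit(test_contexts, "", fixed = TRUE)),
               nrow = length(test_contexts), byrow = TRUE)
  d <- vapply(seq_len(nrow(te)), function(j)
    rowSums(tr != matrix(te[j, ], nrow(tr), w, byrow = TRUE)),
    numeric(nrow(tr)))
  list(min = min(d), median = stats::median(d))
}

#' Gene-wise cross-validation of the mixed-effect forest
#'
#' For each fold, fits the model on all guides of the training genes and
#' scores the held-out genes with the fixed-effect prediction, reporting the
#' per-fold median per-gene Spearman correlation (and pooled enrichment /
#' PPV metrics).
#'
#' @param X,Z,cluster,y as in [merf()]
#' @param k folds
#' @param seed seed for the splitter and the forest
#' @param hp,max_iter,tol passed to [merf()]
#' @param ... further arguments to [merf()]
#' @return list with `folds` (per-fold metric rows), `median_spearman`
#'   (median across all held-out genes pooled), `predictions`
#' @export
merf_cv <- function(X, Z, cluster, y, k = 10L, seed = 1L,
                    hp = merf_hyperparams(), max_iter = 10L, tol = 1e-3, ...) {
  folds <- split_genewise(cluster, k = k, seed = seed)
  pred <- rep(NA_real_, length(y))
  rows <- vector("list", k)
  for (f in seq_len(k)) {
    test <- cluster %in% folds[[f]]$held_out_units
    fit <- merf(X[!test, , drop = FALSE],
                if (is.null(Z)) NULL else Z[!test, , drop = FALSE],
                cluster[!test], y[!test], hp = hp, max_iter = max_iter,
                tol = tol, seed = seed, ...)
    pred[test] <- predict(fit, X[test, , drop = FALSE], type = "fixed")
    sp <- suppressMessages(
      per_gene_spearman(pred[test], y[test], cluster[test]))
    rows[[f]] <- data.frame(fold = f, n_test = sum(test),
                            n_genes = length(folds[[f]]$held_out_units),
                            median_spearman = sp$median)
  }
  all_sp <- suppressMessages(per_gene_spearman(pred, y, cluster))
  list(folds = do.call(rbind, rows),
       median_spearman = all_sp$median,
       per_gene = all_sp$per_gene,
       predictions = pred)
}
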