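# Cross-screen data fusion: put depletion logFCs from independent screens on
# a common scale and derive gene-normalized per-guide activity scores.

#' Average logFCs of two screens sharing a guide library
#'
#' For screens performed with the same library (e.g., the same plasmid pool
#' under two promoter strengths) the shared scale is the elementwise mean of
#' the two logFC maps over the guide intersection.
#'
#' @param lfc_a,lfc_b named numeric vectors, names are guide ids
#' @return named numeric vector over the common guides
#' @export
average_shared_library <- function(lfc_a, lfc_b) {
  common <- intersect(names(lfc_a), names(lfc_b))
  if (length(common) == 0L)
    stop("no shared guides between the two libraries", call. = FALSE)
  n_miss <- length(union(names(lfc_a), names(lfc_b))) - length(common)
  if (n_miss > 0L)
    message(n_miss, " guide(s) present in only one library were dropped")
  (lfc_a[common] + lfc_b[common]) / 2
}

#' Fit a linear scaling between two screens from overlapping guides
#'
#' Ordinary least squares of the reference-scale values on the screen to be
#' rescaled: the fitted map `scaled = slope * logfc + intercept` places the
#' second screen on the reference scale.
#'
#' @param x logFCs in the screen to be rescaled (e.g., an independent library)
#' @param y reference-scale logFCs for the same guides
#' @return list of class `logfc_scaling` with `slope` and `intercept`
#' @export
fit_scaling <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(unique(x)) < 2L || stats::var(x) == 0)
    stop("degenerate x: need >= 2 distinct values to fit a scaling",
         call. = FALSE)
  fit <- stats::lm(y ~ x)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 n = length(x)), class = "logfc_scaling")
}

#' @export
print.logfc_scaling <- function(x, ...) {
  cat("<logfc_scaling> scaled = ", signif(x$slope, 4), " * logfc + ",
      signif(x$intercept, 4), "  (fit on ", x$n, " overlapping guides)\n",
      sep = "")
  invisible(x)
}

#' Rescale a screen and drop its overlap with the reference library
#'
#' Applies a fitted [fit_scaling()] to every observation of the screen and
#' removes the guides used to fit the scaling (they are already represented
#' on the reference scale), so no guide is double-counted in training.
#'
#' @param obs data.frame with columns `guide_id` and `logfc`
#' @param scaling a `logfc_scaling`
#' @param overlap_ids guide ids to drop after rescaling
#' @return `obs` with a `scaled_logfc` column, overlap rows removed
#' @export
apply_scaling_and_drop_overlap <- function(obs, scaling, overlap_ids = character()) {
  stopifnot(inherits(scaling, "logfc_scaling"))
  obs$scaled_logfc <- scaling$slope * obs$logfc + scaling$intercept
  out <- obs[!obs$guide_id %in% overlap_ids, , drop = FALSE]
  if (nrow(out) == 0L)
    warning("all observations were in the overlap set; returning empty screen")
  rownames(out) <- NULL
  out
}

#' Per-guide activity scores from scaled logFCs
#'
#' Genes represented by fewer than `min_guides` guides in a dataset are
#' dropped (their median would be unstable); each remaining guide's activity
#' is its scaled logFC minus the per-gene median scaled logFC, pooled over
#' datasets by default.  Negative activity identifies guides depleting more
#' strongly than the typical guide of their gene, i.e. efficient guides.
#'
#' @param obs data.frame with columns `guide_id`, `gene_id`, `dataset`,
#'   `scaled_logfc`
#' @param min_guides minimum guides per (gene, dataset) group
#' @param pool_datasets if `TRUE` (default) the per-gene median pools all
#'   retained datasets; otherwise it is computed within each dataset
#' @return `obs` restricted to retained rows, with an `activity_score` column
#' @export
activity_scores <- function(obs, min_guides = 5L, pool_datasets = TRUE) {
  stopifnot(all(c("guide_id", "gene_id", "dataset", "scaled_logfc") %in%
                  names(obs)))
  grp <- paste(obs$gene_id, obs$dataset, sep = "\r")
  keep <- ave(seq_along(grp), grp, FUN = length) >= min_guides
  out <- obs[keep, , drop = FALSE]
  med_key <- if (pool_datasets) out$gene_id else
    paste(out$gene_id, out$dataset, sep = "\r")
  med <- ave(out$scaled_logfc, med_key, FUN = stats::median)
  out$activity_score <- out$scaled_logfc - med
  rownames(out) <- NULL
  out
}

#' Assemble the mixed-model training table from fused screens
#'
#' One row per (guide, dataset) observation: a guide assayed in two screens
#' contributes two rows sharing the same gene cluster.  The gene id is the
#' cluster id for the random-effect model.
#'
#' @param datasets list of data.frames, each with `guide_id`, `gene_id`,
#'   `dataset`, `logfc` and optionally `scaled_logfc` / `activity_score`
#' @return data.frame with a `cluster` column (= `gene_id`)
#' @export
assemble_training_table <- function(datasets) {
  tab <- do.call(rbind, lapply(datasets, function(d) {
    d[, intersect(c("guide_id", "gene_id", "dataset", "logfc",
                    "scaled_logfc", "activity_score"), names(d)),
      drop = FALSE]
  }))
  key <- paste(tab$guide_id, tab$dataset, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (guide, dataset) rows: ",
         paste(head(tab$guide_id[duplicated(key)], 3), collapse = ", "),
         call. = FALSE)
  tab$cluster <- tab$gene_id
  rownames(tab) <- NULL
  tab
}
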