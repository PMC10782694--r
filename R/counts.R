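# From guide x sample read counts to per-guide logFCs: CPM filtering,
# TMM normalization factors computed on the non-targeting controls, and a
# normalized log-ratio depletion estimator with replicate averaging.

#' Construct a guide x sample count matrix container
#'
#' @param counts non-negative integer matrix, guides x samples
#' @param sample_meta data.frame with columns `sample`, `timepoint`,
#'   `replicate`, `is_input` (row per sample, in column order)
#' @param guide_meta data.frame with columns `guide_id`, `gene_id`,
#'   `is_nontargeting` (row per guide, in row order)
#' @return list of class `count_matrix`
#' @export
count_matrix <- function(counts, sample_meta, guide_meta) {
  counts <- as.matrix(counts)
  stopifnot(nrow(sample_meta) == ncol(counts),
            nrow(guide_meta) == nrow(counts),
            all(counts >= 0),
            all(c("sample", "timepoint", "replicate", "is_input") %in%
                  names(sample_meta)),
            all(c("guide_id", "gene_id", "is_nontargeting") %in%
                  names(guide_meta)))
  if (any(colSums(counts) == 0)) stop("sample with zero total counts",
                                      call. = FALSE)
  if (!any(sample_meta$is_input)) stop("need at least one input sample",
                                       call. = FALSE)
  if (!any(guide_meta$is_nontargeting))
    stop("need at least one non-targeting guide for normalization",
         call. = FALSE)
  structure(list(counts = counts, sample_meta = sample_meta,
                 guide_meta = guide_meta), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("<count_matrix> ", nrow(x$counts), " guides (",
      sum(x$guide_meta$is_nontargeting), " non-targeting) x ",
      ncol(x$counts), " samples\n", sep = "")
  invisible(x)
}

#' Filter guides by counts-per-million abundance
#'
#' Keeps guides with CPM >= `min_cpm` in at least `min_samples` samples
#' (inclusive bounds); CPM is computed against the raw column totals.
#'
#' @param cm a [count_matrix()]
#' @param min_cpm CPM threshold
#' @param min_samples number of samples required at or above the threshold
#' @return the filtered [count_matrix()]
#' @export
cpm_filter <- function(cm, min_cpm = 1, min_samples = 4L) {
  stopifnot(inherits(cm, "count_matrix"))
  cpm <- sweep(cm$counts, 2L, colSums(cm$counts), "/") * 1e6
  keep <- rowSums(cpm >= min_cpm) >= min_samples
  if (!any(keep)) stop("all guides removed by the CPM filter", call. = FALSE)
  count_matrix(cm$counts[keep, , drop = FALSE], cm$sample_meta,
               cm$guide_meta[keep, , drop = FALSE])
}

#' Per-sample normalization factors from non-targeting guides
#'
#' Trimmed-mean-of-M-values (TMM) factors computed on the non-targeting
#' control guides only, against the first input sample as reference, with
#' library sizes taken from the full column totals (30% M-trim, 5% A-trim).
#' Factors are normalized to geometric mean 1; dividing a sample's library
#' size-normalized counts by its factor centres the non-targeting guides at
#' logFC ~ 0.
#'
#' @param cm a [count_matrix()]
#' @param logratio_trim,sum_trim TMM trim fractions
#' @return named numeric vector of factors (one per sample)
#' @export
nontargeting_norm_factors <- function(cm, logratio_trim = 0.3,
                                      sum_trim = 0.05) {
  stopifnot(inherits(cm, "count_matrix"))
  nt <- cm$guide_meta$is_nontargeting
  if (sum(nt) < 5L)
    stop("need >= 5 non-targeting guides, have ", sum(nt), call. = FALSE)
  ref <- which(cm$sample_meta$is_input)[1]
  f <- edgeR::calcNormFactors(cm$counts[nt, , drop = FALSE],
                              lib.size = colSums(cm$counts),
                              method = "TMM", refColumn = ref,
                              logratioTrim = logratio_trim,
                              sumTrim = sum_trim)
  stats::setNames(as.numeric(f), cm$sample_meta$sample)
}

#' Per-guide logFC between output time points and the input library
#'
#' For each time point and replicate, the log2 ratio of pseudo-counted,
#' factor- and depth-normalized abundances against the matched input
#' replicate, averaged over replicates:
#' `logFC = mean_r log2( (out + p) / (Nf_out) / ((in + p) / (Nf_in)) )`
#' with `Nf = factor * library size`.  The median logFC of the
#' non-targeting guides is attached as a calibration statistic (near 0
#' after normalization).
#'
#' @param cm a [count_matrix()]
#' @param factors per-sample factors from [nontargeting_norm_factors()]
#' @param pseudo pseudo-count guarding zeros
#' @return data.frame (guide_id, gene_id, timepoint, logfc) with attribute
#'   `nontargeting_median`
#' @export
estimate_logfc <- function(cm, factors = nontargeting_norm_factors(cm),
                           pseudo = 0.5) {
  stopifnot(inherits(cm, "count_matrix"))
  sm <- cm$sample_meta
  if (!any(sm$is_input)) stop("missing input sample", call. = FALSE)
  eff_lib <- colSums(cm$counts) * factors[sm$sample]
  norm <- sweep(cm$counts + pseudo, 2L, eff_lib, "/")
  tps <- unique(sm$timepoint[!sm$is_input])
  out <- lapply(tps, function(tp) {
    reps <- sort(unique(sm$replicate[sm$timepoint == tp]))
    lfc_reps <- vapply(reps, function(r) {
      o <- which(sm$timepoint == tp & sm$replicate == r)
      i <- which(sm$is_input & sm$replicate == r)
      if (length(i) == 0L) i <- which(sm$is_input)[1]  # unpaired input
      log2(norm[, o[1]] / norm[, i[1]])
    }, numeric(nrow(cm$counts)))
    data.frame(guide_id = cm$guide_meta$guide_id,
               gene_id = cm$guide_meta$gene_id,
               timepoint = tp,
               logfc = rowMeans(lfc_reps),
               is_nontargeting = cm$guide_meta$is_nontargeting,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "nontargeting_median") <-
    stats::median(res$logfc[res$is_nontargeting])
  res
}
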