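#' Canonical feature registry for guide and gene features
#'
#' The model distinguishes 129 guide-level (fixed-effect) features from 9
#' gene/dataset-level (random-effect) features.  The fixed block is made of a
#' 120-column one-hot encoding of the 30-nt target context (positions -4..-1
#' upstream of the guide, G1..G20 guide, P1..P3 PAM, +1..+3 downstream; channel
#' order A,C,G,T), four hybridization/folding energies, three distance
#' features, the longest homopolymer run, and an indicator for guides
#' targeting the first gene of a transcription unit.  The random block holds
#' expression, gene architecture and dataset-indicator features.
#'
#' @return A list of class `feature_registry` with elements `fixed_names`
#'   (length 129), `random_names` (length 9), `context_labels` (length 30)
#'   and `bases` (`A`,`C`,`G`,`T`).
#' @examples
#' reg <- feature_registry()
#' length(reg$fixed_names)  # 129
#' length(reg$random_names) # 9
#' @export
feature_registry <- function() {
  labels <- context_position_labels()
  bases <- c("A", "C", "G", "T")
  onehot <- as.vector(t(outer(labels, bases, paste, sep = "_")))
  fixed <- c(onehot,
             "mfe_monomer", "mfe_homodimer", "mfe_hybrid", "mfe_seed_hybrid",
             "dist_start_codon", "rel_dist", "dist_tu_start",
             "homopolymer", "targets_first_gene")
  random <- c("expr_min", "expr_max", "gene_gc", "gene_length",
              "n_downstream_genes", "n_downstream_essential", "cai",
              "dataset_ind_1", "dataset_ind_2")
  stopifnot(length(fixed) == 129L, length(random) == 9L)
  structure(list(fixed_names = fixed, random_names = random,
                 context_labels = labels, bases = bases),
            class = "feature_registry")
}

context_position_labels <- function() {
  c(paste0("-", 4:1), paste0("G", 1:20), paste0("P", 1:3), paste0("+", 1:3))
}

#' @export
print.feature_registry <- function(x, ...) {
  cat("Feature registry: ", length(x$fixed_names), " fixed (guide) + ",
      length(x$random_names), " random (gene/dataset) features\n", sep = "")
  invisible(x)
}

check_dna <- function(s, what = "sequence") {
  bad <- grepl("[^ACGT]", s)
  if (any(bad)) {
    stop(what, " contains non-ACGT characters: ",
         paste(unique(unlist(strsplit(gsub("[ACGT]", "", s[bad]), ""))),
               collapse = ", "), call. = FALSE)
  }
  invisible(s)
}

#' Reverse complement of DNA strings (base implementation, vectorized)
#' @param s character vector of ACGT strings
#' @return character vector of reverse complements
#' @export
revcomp <- function(s) {
  check_dna(s)
  vapply(strsplit(chartr("ACGT", "TGCA", s), "", fixed = TRUE),
         function(x) paste(rev(x), collapse = ""), character(1))
}

gc_fraction <- function(s) {
  vapply(s, function(x) {
    n <- nchar(x)
    (n - nchar(gsub("[GC]", "", x))) / n
  }, numeric(1), USE.NAMES = FALSE)
}

#' One-hot encode a 30-nt target context
#'
#' Position-major layout with channel order A,C,G,T: entry `4*(pos-1)+channel`
#' is 1 when the base at `pos` equals the channel base.
#'
#' @param context30 a single 30-character ACGT string
#' @return named numeric vector of length 120 (one 1 per 4-block)
#' @export
one_hot_context <- function(context30) {
  if (length(context30) != 1L || !is.character(context30))
    stop("context30 must be a single string", call. = FALSE)
  if (nchar(context30) != 30L)
    stop("context30 must have length 30, got ", nchar(context30), call. = FALSE)
  chars <- strsplit(context30, "", fixed = TRUE)[[1]]
  bases <- c("A", "C", "G", "T")
  idx <- match(chars, bases)
  if (anyNA(idx))
    stop("invalid base at position ", which(is.na(idx))[1], ": '",
         chars[which(is.na(idx))[1]], "'", call. = FALSE)
  v <- numeric(120)
  v[4L * (seq_len(30L) - 1L) + idx] <- 1
  names(v) <- as.vector(t(outer(context_position_labels(), bases, paste, sep = "_")))
  v
}

#' Decode a 120-length one-hot vector back to its 30-nt context
#' @param v numeric vector of length 120 as produced by [one_hot_context()]
#' @return the 30-character string
#' @export
decode_one_hot <- function(v) {
  stopifnot(length(v) == 120L)
  m <- matrix(v, nrow = 4L)
  if (!all(colSums(m) == 1))
    stop("not a valid one-hot encoding", call. = FALSE)
  paste(c("A", "C", "G", "T")[apply(m, 2L, which.max)], collapse = "")
}

# One-hot encode many contexts at once; rows in input order.
one_hot_matrix <- function(contexts) {
  n <- length(contexts)
  stopifnot(all(nchar(contexts) == 30L))
  chars <- matrix(unlist(strsplit(contexts, "", fixed = TRUE)), nrow = n, byrow = TRUE)
  idx <- match(chars, c("A", "C", "G", "T"))
  if (anyNA(idx)) stop("invalid base in context sequences", call. = FALSE)
  idx <- matrix(idx, nrow = n)
  out <- matrix(0, n, 120L)
  cols <- sweep(idx, 2L, 4L * (seq_len(30L) - 1L), "+")
  out[cbind(rep(seq_len(n), 30L), as.vector(cols))] <- 1
  colnames(out) <- as.vector(t(outer(context_position_labels(),
                                     c("A", "C", "G", "T"), paste, sep = "_")))
  out
}

#' Longest homopolymer run in a guide sequence
#'
#' @param spacer non-empty ACGT string (or vector of strings)
#' @return integer vector: length of the longest single-nucleotide run
#' @examples
#' homopolymer("AAAAACGTACGTACGTACGT") # 5
#' @export
homopolymer <- function(spacer) {
  if (any(nchar(spacer) == 0L)) stop("empty sequence", call. = FALSE)
  check_dna(spacer, "spacer")
  vapply(strsplit(spacer, "", fixed = TRUE),
         function(x) max(rle(x)$lengths), integer(1))
}

#' Codon adaptation index of a coding sequence
#'
#' Geometric mean of per-codon relative adaptiveness weights, excluding stop
#' codons and the single-codon amino acids Met (ATG) and Trp (TGG).
#'
#' @param cds in-frame ACGT coding sequence (length divisible by 3)
#' @param weights named numeric map codon -> relative adaptiveness in (0,1];
#'   must cover all sense codons with the best codon of each amino acid at 1
#' @return CAI in (0, 1]
#' @export
compute_cai <- function(cds, weights) {
  check_dna(cds, "cds")
  if (nchar(cds) %% 3L != 0L) stop("CDS length not divisible by 3", call. = FALSE)
  codons <- substring(cds, seq(1L, nchar(cds) - 2L, by = 3L),
                      seq(3L, nchar(cds), by = 3L))
  gc <- Biostrings::GENETIC_CODE
  aa <- gc[codons]
  if (anyNA(aa)) stop("unknown codon: ", codons[which(is.na(aa))[1]], call. = FALSE)
  single <- names(table(gc[gc != "*"]))[table(gc[gc != "*"]) == 1L]
  keep <- aa != "*" & !(aa %in% single)
  codons <- codons[keep]
  if (length(codons) == 0L) stop("no scorable codons in CDS", call. = FALSE)
  w <- weights[codons]
  if (anyNA(w)) stop("weights missing for codon: ",
                     codons[which(is.na(w))[1]], call. = FALSE)
  exp(mean(log(w)))
}

#' Relative-adaptiveness codon weights from observed usage
#'
#' Counts codon usage over a set of coding sequences and returns, per codon,
#' its count divided by the count of the most-used synonymous codon.  A small
#' floor keeps unobserved codons scorable.
#'
#' @param cds_list character vector of in-frame coding sequences
#' @param floor minimum weight assigned to unobserved codons
#' @return named numeric vector over all 61 sense codons
#' @export
codon_weights_from_usage <- function(cds_list, floor = 0.01) {
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  counts <- setNames(numeric(length(sense)), sense)
  for (cds in cds_list) {
    codons <- substring(cds, seq(1L, nchar(cds) - 2L, by = 3L),
                        seq(3L, nchar(cds), by = 3L))
    tab <- table(codons[codons %in% sense])
    counts[names(tab)] <- counts[names(tab)] + tab
  }
  aa <- gc[sense]
  w <- counts
  for (a in unique(aa)) {
    i <- aa == a
    m <- max(counts[i])
    w[i] <- if (m > 0) counts[i] / m else 1
  }
  pmax(w, floor)
}

#' Gene-level (random-effect) feature vector
#'
#' Expression minima/maxima are taken over the optical densities up to the OD
#' at which the screen was collected (`od_cap`); the dataset enters as two
#' treatment-coded indicators against the reference dataset.
#'
#' @param gene a [gene_annotation()] object
#' @param dataset_label dataset of the observation
#' @param od_cap largest OD included when summarizing expression (`Inf` = all)
#' @param datasets ordered dataset universe; first element is the reference
#'   level coded (0,0)
#' @return named numeric vector of length 9 in registry order
#' @export
gene_feature_vector <- function(gene, dataset_label, od_cap = Inf,
                                datasets = c("E75", "E18", "Wang")) {
  expr <- gene$expression_by_od
  if (length(expr) == 0L) stop("expression_by_od is empty", call. = FALSE)
  ods <- as.numeric(names(expr))
  use <- ods <= od_cap
  if (!any(use)) stop("no OD <= od_cap (", od_cap, ") for gene ",
                      gene$gene_id, call. = FALSE)
  if (!dataset_label %in% datasets)
    stop("unknown dataset label '", dataset_label, "'", call. = FALSE)
  ind <- as.numeric(seq_along(datasets)[-1] == match(dataset_label, datasets))
  if (length(ind) != 2L) ind <- rep_len(ind, 2L)
  c(expr_min = min(expr[use]), expr_max = max(expr[use]),
    gene_gc = gene$gc_content, gene_length = gene$length_nt,
    n_downstream_genes = gene$n_downstream_genes,
    n_downstream_essential = gene$n_downstream_essential,
    cai = gene$cai, dataset_ind_1 = ind[1], dataset_ind_2 = ind[2])
}
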