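#' Construct a gene annotation record
#'
#' Bundles the per-gene information the featurizer needs: the coding sequence,
#' genomic coordinates, transcription-unit (TU) context, essentiality, an
#' expression profile over growth (OD -> expression) and the codon adaptation
#' index.  GC content and length are derived from the sequence and validated.
#'
#' @param gene_id gene identifier
#' @param coding_sequence mRNA-sense ACGT coding sequence
#' @param genomic_start,genomic_end 1-based inclusive chromosome coordinates
#' @param strand `"+"` or `"-"`
#' @param tu_id transcription unit identifier
#' @param index_in_tu 0-based rank of the gene within its TU (0 = first)
#' @param n_downstream_genes,n_downstream_essential counts of (essential)
#'   genes downstream in the same TU
#' @param is_essential logical essentiality label
#' @param expression_by_od named numeric vector, names are ODs
#' @param cai codon adaptation index in \[0,1\]
#' @param tu_offset nt from the TU start to the gene start (>= 0)
#' @return list of class `gene_annotation`
#' @export
gene_annotation <- function(gene_id, coding_sequence, genomic_start, genomic_end,
                            strand = "+", tu_id = gene_id, index_in_tu = 0L,
                            n_downstream_genes = 0L, n_downstream_essential = 0L,
                            is_essential = FALSE, expression_by_od = c("1" = 1),
                            cai = 1, tu_offset = 0L) {
  check_dna(coding_sequence, paste0("coding sequence of ", gene_id))
  L <- nchar(coding_sequence)
  stopifnot(L > 0L, index_in_tu >= 0L, n_downstream_genes >= 0L,
            n_downstream_essential >= 0L, tu_offset >= 0L,
            strand %in% c("+", "-"), cai >= 0, cai <= 1)
  structure(list(
    gene_id = gene_id, coding_sequence = coding_sequence,
    genomic_start = genomic_start, genomic_end = genomic_end, strand = strand,
    tu_id = tu_id, index_in_tu = as.integer(index_in_tu),
    n_downstream_genes = as.integer(n_downstream_genes),
    n_downstream_essential = as.integer(n_downstream_essential),
    is_essential = isTRUE(is_essential),
    expression_by_od = expression_by_od, cai = cai,
    gc_content = gc_fraction(coding_sequence), length_nt = L,
    tu_offset = as.integer(tu_offset)), class = "gene_annotation")
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat("<gene_annotation> ", x$gene_id, ": ", x$length_nt, " nt, TU ", x$tu_id,
      " (rank ", x$index_in_tu, "), GC ", round(x$gc_content, 3), "\n", sep = "")
  invisible(x)
}

#' Enumerate candidate CRISPRi guides on the coding strand of a gene
#'
#' Scans the mRNA-sense sequence for `CCN` PAM placements (the reverse
#' complement of an `NGG` PAM seen in protospacer orientation): the guide then
#' anneals to the coding (non-template) strand, the convention required for
#' CRISPRi within open reading frames.  For a `CC` starting at sense position
#' *s* (0-based, relative to the first base of the start codon) the
#' protospacer occupies sense positions *s*+3..*s*+22 and must lie inside the
#' CDS; the reported 30-nt context (4 nt upstream, 20-nt target, NGG PAM,
#' 3 nt downstream, in protospacer orientation) is drawn from `genome_context`
#' and may extend into the flanks.
#'
#' Guides are filtered to GC content within `[gc_min, gc_max]` (inclusive) on
#' the 20-nt spacer and must not contain any `forbidden_motifs` on either
#' strand (default: BbsI recognition sites, which would interfere with
#' Golden-Gate library cloning).
#'
#' @param gene a [gene_annotation()]
#' @param genome_context mRNA-sense sequence containing the CDS plus flanks
#'   (>= 7 nt on each side to recover every context)
#' @param cds_offset 0-based offset of the CDS start within `genome_context`;
#'   if `NULL` the coding sequence is located by exact match
#' @param gc_min,gc_max inclusive GC bounds on the spacer
#' @param forbidden_motifs DNA motifs excluded from the spacer and its
#'   reverse complement
#' @return data.frame (class `guide_sites`) with one row per site, sorted by
#'   `dist_start_codon` (0-based offset of the PAM-distal protospacer end,
#'   G1, from the first base of the start codon)
#' @export
enumerate_guides <- function(gene, genome_context, cds_offset = NULL,
                             gc_min = 0.30, gc_max = 0.85,
                             forbidden_motifs = c("GAAGAC", "GTCTTC")) {
  check_dna(genome_context, paste0("genome context of ", gene$gene_id))
  L <- gene$length_nt
  if (is.null(cds_offset)) {
    hits <- gregexpr(gene$coding_sequence, genome_context, fixed = TRUE)[[1]]
    if (length(hits) != 1L || hits[1] == -1L)
      stop("coding sequence of ", gene$gene_id,
           " not found uniquely in genome_context", call. = FALSE)
    cds_offset <- hits[1] - 1L
  }
  ctx_chars <- strsplit(genome_context, "", fixed = TRUE)[[1]]
  nc <- length(ctx_chars)
  # candidate CC dinucleotides anywhere in the context (1-based position c)
  cc <- which(ctx_chars == "C")
  cc <- cc[cc < nc & ctx_chars[cc + 1L] == "C"]
  # protospacer sense span c+3 .. c+22 must fall within the CDS
  lo <- cds_offset + 1L
  hi <- cds_offset + L
  cand <- cc[cc + 3L >= lo & cc + 22L <= hi]
  # full 30-nt context needs positions c-3 .. c+26
  have_ctx <- cand - 3L >= 1L & cand + 26L <= nc
  if (any(!have_ctx)) {
    message(sum(!have_ctx), " site(s) in ", gene$gene_id,
            " skipped: flank too short for the 30-nt context")
    cand <- cand[have_ctx]
  }
  if (length(cand) == 0L) return(empty_guide_sites())
  sense20 <- substring(genome_context, cand + 3L, cand + 22L)
  sense30 <- substring(genome_context, cand - 3L, cand + 26L)
  spacer <- revcomp(sense20)
  context30 <- revcomp(sense30)
  gc <- gc_fraction(spacer)
  keep <- gc >= gc_min & gc <= gc_max
  if (length(forbidden_motifs)) {
    both <- c(forbidden_motifs, revcomp(forbidden_motifs))
    hit <- Reduce(`|`, lapply(both, function(m) grepl(m, spacer, fixed = TRUE)))
    keep <- keep & !hit
  }
  if (!any(keep)) return(empty_guide_sites())
  cand <- cand[keep]
  dist <- cand + 22L - lo  # 0-based offset of G1 from the start codon
  out <- data.frame(
    guide_id = paste0(gene$gene_id, "_g", dist),
    gene_id = gene$gene_id,
    spacer = spacer[keep],
    context30 = context30[keep],
    pam = substring(context30[keep], 25L, 27L),
    dist_start_codon = dist,
    rel_dist = dist / L,
    dist_tu_start = dist + gene$tu_offset,
    targets_first_gene = gene$index_in_tu == 0L,
    gc = gc[keep],
    stringsAsFactors = FALSE)
  out <- out[order(out$dist_start_codon), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("guide_sites", "data.frame")
  out
}

empty_guide_sites <- function() {
  out <- data.frame(guide_id = character(), gene_id = character(),
                    spacer = character(), context30 = character(),
                    pam = character(), dist_start_codon = integer(),
                    rel_dist = numeric(), dist_tu_start = integer(),
                    targets_first_gene = logical(), gc = numeric(),
                    stringsAsFactors = FALSE)
  class(out) <- c("guide_sites", "data.frame")
  out
}

#' Distance features of a guide site
#'
#' @param site one row of a `guide_sites` data.frame (or a list with
#'   `dist_start_codon`)
#' @param gene the targeted [gene_annotation()]
#' @return list with `dist_start_codon`, `rel_dist`, `dist_tu_start` and
#'   `targets_first_gene`
#' @export
distance_features <- function(site, gene) {
  d <- site$dist_start_codon
  if (length(d) != 1L || d < 0L || d >= gene$length_nt)
    stop("site outside the coding region of ", gene$gene_id, call. = FALSE)
  list(dist_start_codon = d,
       rel_dist = d / gene$length_nt,
       dist_tu_start = d + gene$tu_offset,
       targets_first_gene = gene$index_in_tu == 0L)
}

#' Assemble fixed- and random-effect feature matrices for observations
#'
#' Builds the n x 129 guide (fixed) block in registry order and the n x 9
#' gene/dataset (random) block, the latter standardized column-wise to zero
#' mean and unit population variance (constant columns are mapped to zero).
#'
#' @param sites `guide_sites` data.frame covering every observed guide
#' @param genes named list of [gene_annotation()] objects
#' @param observations data.frame with columns `guide_id`, `gene_id`,
#'   `dataset` (row order is preserved)
#' @param registry a [feature_registry()]
#' @param engine thermodynamics engine (see [thermo_engine_nn()])
#' @param od_cap named numeric: per-dataset OD cap for expression summaries
#' @param datasets ordered dataset universe for the treatment coding
#' @return list of class `feature_matrix`: `fixed` (n x 129), `random`
#'   (n x 9, standardized), `random_raw`, `scaler`, `registry`
#' @export
build_feature_matrix <- function(sites, genes, observations,
                                 registry = feature_registry(),
                                 engine = thermo_engine_nn(),
                                 od_cap = c(E75 = Inf, E18 = Inf, Wang = 1.4),
                                 datasets = c("E75", "E18", "Wang")) {
  m <- match(observations$guide_id, sites$guide_id)
  if (anyNA(m))
    stop("observations reference unknown guide_ids: ",
         paste(head(unique(observations$guide_id[is.na(m)]), 5), collapse = ", "),
         call. = FALSE)
  missing_genes <- setdiff(unique(observations$gene_id), names(genes))
  if (length(missing_genes))
    stop("missing gene annotations for: ",
         paste(missing_genes, collapse = ", "), call. = FALSE)
  s <- sites[m, , drop = FALSE]

  oh <- one_hot_matrix(s$context30)
  th <- thermo_features_matrix(s$spacer, s$context30, engine)
  fixed <- cbind(oh, th,
                 dist_start_codon = s$dist_start_codon,
                 rel_dist = s$rel_dist,
                 dist_tu_start = s$dist_tu_start,
                 homopolymer = as.numeric(homopolymer(s$spacer)),
                 targets_first_gene = as.numeric(s$targets_first_gene))
  colnames(fixed) <- registry$fixed_names

  key <- paste(observations$gene_id, observations$dataset, sep = "\r")
  ukey <- !duplicated(key)
  gvec <- matrix(0, sum(ukey), 9L,
                 dimnames = list(key[ukey], registry$random_names))
  for (i in which(ukey)) {
    g <- genes[[observations$gene_id[i]]]
    ds <- as.character(observations$dataset[i])
    cap <- if (ds %in% names(od_cap)) od_cap[[ds]] else Inf
    gvec[key[i], ] <- gene_feature_vector(g, ds, cap, datasets)
  }
  random_raw <- gvec[key, , drop = FALSE]
  rownames(random_raw) <- NULL

  center <- colMeans(random_raw)
  centered <- sweep(random_raw, 2L, center)
  scale <- sqrt(colMeans(centered^2))  # population SD, sklearn convention
  scale[scale == 0] <- 1
  random <- sweep(centered, 2L, scale, "/")

  structure(list(fixed = fixed, random = random, random_raw = random_raw,
                 scaler = list(center = center, scale = scale),
                 registry = registry),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("<feature_matrix> ", nrow(x$fixed), " observations: fixed ",
      ncol(x$fixed), " + random ", ncol(x$random), " features\n", sep = "")
  invisible(x)
}
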