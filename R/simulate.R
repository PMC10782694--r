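# Synthetic CRISPRi depletion screens with a known gene/guide effect
# decomposition.  The generator emulates the structure of pooled essentiality
# screens: genes organized in transcription units with expression profiles
# and essentiality labels; saturating guide sets with 30-nt contexts; a
# gene-level depletion effect coupled to expression and downstream essential
# genes; a guide-level effect driven by PAM-proximal sequence and proximity
# to the start codon; Gaussian logFC noise; and negative-binomial read
# counts anchored by non-targeting controls.

#' Configuration of the synthetic screen generator
#'
#' All standard deviations are on the log2 fold-change scale.  The defaults
#' (and the `"default"` preset of [sim_preset()]) describe a screen of 300
#' genes with 10 guides each, gene-effect SD 2.0, guide-effect SD 1.0 and
#' measurement noise SD 0.5.
#'
#' @param n_genes number of genes
#' @param genes_per_tu genes per transcription unit
#' @param guides_per_gene guides sampled per gene (>= 5 so the fusion
#'   filter keeps every gene)
#' @param gene_length CDS length in nt (multiple of 3)
#' @param sd_gene_effect,sd_guide_effect,sd_noise effect/noise SDs (log2)
#' @param expression_coupling weight of standardized log expression on the
#'   gene effect (higher expression -> stronger depletion)
#' @param distance_bonus extra depletion (log2) for guides within
#'   `distance_window` nt of the start codon
#' @param distance_window window of enhanced silencing (nt)
#' @param seq_weights 30 x 4 matrix of per-position, per-base contributions
#'   to the guide effect (rows = context positions, cols = A,C,G,T); see
#'   [default_seq_weights()]
#' @param essential_frac fraction of genes labelled essential
#' @param nb_dispersion negative-binomial dispersion of read counts
#' @param library_size expected reads per sample
#' @param n_nontargeting non-targeting control guides
#' @param replicate_factor multiplicative depth factor of the second
#'   replicate
#' @param seed RNG seed
#' @return list of class `sim_config`
#' @export
sim_config <- function(n_genes = 300L, genes_per_tu = 2L,
                       guides_per_gene = 10L, gene_length = 600L,
                       sd_gene_effect = 2.0, sd_guide_effect = 1.0,
                       sd_noise = 0.5, expression_coupling = 1.0,
                       distance_bonus = 1.5, distance_window = 60L,
                       seq_weights = default_seq_weights(),
                       essential_frac = 0.5, nb_dispersion = 0.01,
                       library_size = 1e6, n_nontargeting = 50L,
                       replicate_factor = 1.15, seed = 1L) {
  stopifnot(n_genes >= 1L, genes_per_tu >= 1L, guides_per_gene >= 5L,
            gene_length %% 3L == 0L, sd_gene_effect >= 0, sd_guide_effect >= 0,
            sd_noise >= 0, nb_dispersion >= 0, library_size > 0,
            n_nontargeting >= 0L, nrow(seq_weights) == 30L,
            ncol(seq_weights) == 4L)
  structure(as.list(environment()), class = "sim_config")
}

#' Named simulator presets
#' @param name preset name (`"default"`: 300 genes x 10 guides, effect SDs
#'   2.0 / 1.0 / 0.5, seed 7; `"small"`: a fast 60-gene variant of the same
#'   conditions; `"no_gene_effect"`: gene-effect SD 0)
#' @return a [sim_config()]
#' @export
sim_preset <- function(name = c("default", "small", "no_gene_effect")) {
  name <- match.arg(name)
  switch(name,
    default = sim_config(n_genes = 300L, guides_per_gene = 10L,
                         sd_gene_effect = 2.0, sd_guide_effect = 1.0,
                         sd_noise = 0.5, seed = 7L),
    small = sim_config(n_genes = 60L, guides_per_gene = 10L,
                       sd_gene_effect = 2.0, sd_guide_effect = 1.0,
                       sd_noise = 0.5, seed = 7L),
    no_gene_effect = sim_config(n_genes = 300L, guides_per_gene = 10L,
                                sd_gene_effect = 0, expression_coupling = 0,
                                sd_guide_effect = 1.0, sd_noise = 0.5,
                                seed = 7L))
}

#' Default sequence weights of the simulated guide effect
#'
#' Mostly-zero 30 x 4 matrix mimicking the qualitative sequence preferences
#' seen around the PAM in CRISPRi screens: cytosine at the variable PAM
#' position (P1) and directly downstream of the PAM (+1) favours silencing
#' (negative weight = stronger depletion), guanosine at +1 and
#' adenine/guanine at guide position G20 disfavour it, plus smaller
#' seed-region contributions.
#'
#' @return 30 x 4 numeric matrix (rows = context positions -4..+3,
#'   cols = A,C,G,T)
#' @export
default_seq_weights <- function() {
  w <- matrix(0, 30L, 4L,
              dimnames = list(context_position_labels(),
                              c("A", "C", "G", "T")))
  w["P1", "C"] <- -0.8
  w["+1", "C"] <- -0.8
  w["+1", "G"] <- 0.8
  w["G20", ] <- c(1.0, -0.4, 0.5, -0.4)
  seed_pos <- paste0("G", 13:19)
  w[seed_pos, "C"] <- -0.7
  w[seed_pos, "A"] <- 0.7
  w["-1", "G"] <- -0.4
  w["-2", "T"] <- 0.4
  w["P3", ] <- 0  # fixed G in valid guides; kept explicit
  w
}

#' Simulate a synthetic genome with transcription-unit structure
#'
#' Genes of uniform base composition are laid head-to-tail within
#' transcription units (separated by 60-nt intergenic spacers) along a
#' single chromosome; each gene receives a log-normal expression profile
#' over 10 ODs, an essentiality label, and a codon adaptation index
#' computed from the pooled codon usage of the simulated CDSs.
#'
#' @param cfg a [sim_config()]
#' @return list of class `sim_genome`: `genes` (named list of
#'   [gene_annotation()]), `chromosome` (single DNA string), `tu_table`,
#'   `expression` (genes x ODs matrix), `essential` (named logical)
#' @export
simulate_genome <- function(cfg = sim_config()) {
  restore <- local_rng(cfg$seed)
  on.exit(restore())
  n <- cfg$n_genes
  gene_ids <- sprintf("gene%03d", seq_len(n))
  tu_of <- (seq_len(n) - 1L) %/% cfg$genes_per_tu
  tu_ids <- sprintf("TU%03d", tu_of + 1L)
  idx_in_tu <- (seq_len(n) - 1L) %% cfg$genes_per_tu
  essential <- stats::runif(n) < cfg$essential_frac
  names(essential) <- gene_ids

  cds <- vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), cfg$gene_length, replace = TRUE),
          collapse = ""), character(1))

  ods <- seq(0.2, 2.0, by = 0.2)
  base_expr <- stats::rlnorm(n, meanlog = 3, sdlog = 1)
  expression <- outer(base_expr, rep(1, length(ods))) *
    matrix(stats::rlnorm(n * length(ods), 0, 0.2), n)
  dimnames(expression) <- list(gene_ids, format(ods))

  weights <- codon_weights_from_usage(cds)
  spacer_nt <- 60L
  genes <- vector("list", n)
  pos <- 1L
  chrom <- character(0)
  for (i in seq_len(n)) {
    if (idx_in_tu[i] == 0L) {
      chrom <- c(chrom, paste(sample(c("A", "C", "G", "T"), spacer_nt,
                                     replace = TRUE), collapse = ""))
      pos <- pos + spacer_nt
      tu_start <- pos
    }
    downstream <- which(tu_ids == tu_ids[i] & seq_len(n) > i)
    genes[[i]] <- gene_annotation(
      gene_id = gene_ids[i], coding_sequence = cds[i],
      genomic_start = pos, genomic_end = pos + cfg$gene_length - 1L,
      strand = "+", tu_id = tu_ids[i], index_in_tu = idx_in_tu[i],
      n_downstream_genes = length(downstream),
      n_downstream_essential = sum(essential[downstream]),
      is_essential = essential[i],
      expression_by_od = stats::setNames(expression[i, ], colnames(expression)),
      cai = compute_cai(cds[i], weights),
      tu_offset = pos - tu_start)
    chrom <- c(chrom, cds[i])
    pos <- pos + cfg$gene_length
  }
  names(genes) <- gene_ids
  tu_table <- data.frame(tu_id = tu_ids, gene_id = gene_ids,
                         rank = idx_in_tu, stringsAsFactors = FALSE)
  structure(list(genes = genes, chromosome = paste(chrom, collapse = ""),
                 tu_table = tu_table, expression = expression,
                 essential = essential, config = cfg),
            class = "sim_genome")
}

#' Enumerate and subsample guides on a simulated genome
#'
#' Runs [enumerate_guides()] on every simulated gene (flanks taken from the
#' chromosome) and subsamples `guides_per_gene` sites per gene with the
#' configured seed.
#'
#' @param sim a [simulate_genome()] result
#' @param cfg its [sim_config()] (defaults to the one stored in `sim`)
#' @return a `guide_sites` data.frame
#' @export
simulate_guides <- function(sim, cfg = sim$config) {
  restore <- local_rng(cfg$seed + 1L)
  on.exit(restore())
  out <- lapply(sim$genes, function(g) {
    lo <- max(1L, g$genomic_start - 30L)
    ctx <- substr(sim$chromosome, lo, min(nchar(sim$chromosome),
                                          g$genomic_end + 30L))
    sites <- enumerate_guides(g, ctx, cds_offset = g$genomic_start - lo)
    if (nrow(sites) > cfg$guides_per_gene)
      sites <- sites[sort(sample.int(nrow(sites), cfg$guides_per_gene)), ,
                     drop = FALSE]
    sites
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("guide_sites", "data.frame")
  res
}

#' Simulate a depletion screen over enumerated guides
#'
#' Draws the ground-truth decomposition `logFC = gene_effect + guide_effect
#' + noise`: the gene effect couples (negatively) to standardized log
#' expression and to the number of downstream essential genes in the TU,
#' plus `N(0, sd_gene_effect^2)`; the guide effect sums the per-position
#' sequence weights over the 30-nt context, subtracts `distance_bonus` for
#' guides within `distance_window` nt of the start codon, plus
#' `N(0, sd_guide_effect^2)`.
#'
#' @param sim a [simulate_genome()] result
#' @param guides a `guide_sites` data.frame (see [simulate_guides()])
#' @param cfg a [sim_config()]
#' @param dataset dataset label stamped on the observations
#' @return list: `observations` (guide_id, gene_id, dataset, logfc) and
#'   `truth` (class `sim_truth`: `gene_effects`, `guide_effects`, `noise`)
#' @export
simulate_screen <- function(sim, guides, cfg = sim$config, dataset = "E75") {
  restore <- local_rng(cfg$seed + 2L)
  on.exit(restore())
  gene_ids <- names(sim$genes)
  log_expr <- log(apply(sim$expression, 1L, max))
  z <- (log_expr - mean(log_expr)) /
    (if (stats::sd(log_expr) > 0) stats::sd(log_expr) else 1)
  n_down_ess <- vapply(sim$genes, `[[`, integer(1), "n_downstream_essential")
  gene_effects <- -abs(cfg$expression_coupling * z) - 0.3 * n_down_ess +
    stats::rnorm(length(gene_ids), 0, cfg$sd_gene_effect)
  names(gene_effects) <- gene_ids

  chars <- matrix(unlist(strsplit(guides$context30, "", fixed = TRUE)),
                  nrow = nrow(guides), byrow = TRUE)
  base_idx <- match(chars, c("A", "C", "G", "T"))
  w <- cfg$seq_weights
  seq_part <- rowSums(matrix(w[cbind(rep(seq_len(30L), each = nrow(guides)),
                                     base_idx)], nrow = nrow(guides)))
  dist_part <- -cfg$distance_bonus *
    as.numeric(guides$dist_start_codon < cfg$distance_window)
  guide_noise <- stats::rnorm(nrow(guides), 0, cfg$sd_guide_effect)
  guide_effects <- seq_part + dist_part + guide_noise
  names(guide_effects) <- guides$guide_id

  noise <- stats::rnorm(nrow(guides), 0, cfg$sd_noise)
  logfc <- gene_effects[guides$gene_id] + guide_effects + noise
  observations <- data.frame(
    guide_id = guides$guide_id, gene_id = guides$gene_id,
    dataset = dataset, logfc = as.numeric(logfc),
    stringsAsFactors = FALSE)
  truth <- structure(list(
    gene_effects = gene_effects, guide_effects = guide_effects,
    seq_part = stats::setNames(seq_part, guides$guide_id),
    dist_part = stats::setNames(dist_part, guides$guide_id),
    noise = stats::setNames(noise, guides$guide_id),
    config = cfg), class = "sim_truth")
  list(observations = observations, truth = truth)
}

#' Simulate guide x sample read counts for a screen
#'
#' Input samples draw negative-binomial counts around
#' `library_size / n_guides`; output samples scale the input mean by
#' `2^logFC` (and a replicate depth factor for the second replicate).
#' `n_nontargeting` control guides with logFC 0 are appended; they anchor
#' the normalization downstream.
#'
#' @param observations data.frame with `guide_id`, `gene_id`, `logfc`
#' @param cfg a [sim_config()]
#' @return a [count_matrix()] with samples in_rep1, in_rep2, out_rep1,
#'   out_rep2
#' @export
simulate_counts <- function(observations, cfg = sim_config()) {
  restore <- local_rng(cfg$seed + 3L)
  on.exit(restore())
  nt <- cfg$n_nontargeting
  guide_meta <- data.frame(
    guide_id = c(observations$guide_id, sprintf("NT%03d", seq_len(nt))),
    gene_id = c(observations$gene_id, rep(NA_character_, nt)),
    is_nontargeting = c(rep(FALSE, nrow(observations)), rep(TRUE, nt)),
    stringsAsFactors = FALSE)
  logfc <- c(observations$logfc, rep(0, nt))
  ng <- nrow(guide_meta)
  mu_in <- cfg$library_size / ng
  rep_fac <- c(1, cfg$replicate_factor)
  draw <- function(mu) {
    if (cfg$nb_dispersion <= 0) stats::rpois(ng, mu)
    else stats::rnbinom(ng, mu = mu, size = 1 / cfg$nb_dispersion)
  }
  counts <- cbind(
    in_rep1 = draw(rep(mu_in * rep_fac[1], ng)),
    in_rep2 = draw(rep(mu_in * rep_fac[2], ng)),
    out_rep1 = draw(mu_in * rep_fac[1] * 2^logfc),
    out_rep2 = draw(mu_in * rep_fac[2] * 2^logfc))
  rownames(counts) <- guide_meta$guide_id
  sample_meta <- data.frame(
    sample = colnames(counts),
    timepoint = c("input", "input", "t1", "t1"),
    replicate = c(1L, 2L, 1L, 2L),
    is_input = c(TRUE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  count_matrix(counts, sample_meta, guide_meta)
}

#' Write a simulated genome as FASTA + GFF3 + companion tables
#'
#' Emits the chromosome FASTA, a GFF3 of gene features, and TSVs for the TU
#' table, expression profile and essential-gene list — the same dialects the
#' real-data readers consume.
#'
#' @param sim a [simulate_genome()] result
#' @param dir output directory (created if needed)
#' @return invisibly, the written file paths
#' @export
write_sim_genome <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "genome.fa")
  seq <- Biostrings::DNAStringSet(sim$chromosome)
  names(seq) <- "sim_chr"
  Biostrings::writeXStringSet(seq, fa)
  gff <- file.path(dir, "genes.gff3")
  g <- sim$genes
  lines <- c("##gff-version 3",
             vapply(g, function(x) paste(
               "sim_chr", "sim", "gene", x$genomic_start, x$genomic_end, ".",
               x$strand, ".",
               paste0("ID=", x$gene_id, ";tu_id=", x$tu_id,
                      ";index_in_tu=", x$index_in_tu),
               sep = "\t"), character(1)))
  writeLines(lines, gff)
  tu <- file.path(dir, "tu_table.tsv")
  utils::write.table(sim$tu_table, tu, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expr <- file.path(dir, "expression.tsv")
  utils::write.table(data.frame(gene_id = rownames(sim$expression),
                                sim$expression, check.names = FALSE),
                     expr, sep = "\t", quote = FALSE, row.names = FALSE)
  ess <- file.path(dir, "essential.txt")
  writeLines(names(sim$essential)[sim$essential], ess)
  invisible(c(fa, gff, tu, expr, ess))
}

#' Run the simulator end-to-end and featurize for model fitting
#'
#' Convenience wrapper chaining [simulate_genome()], [simulate_guides()],
#' [simulate_screen()] and [build_feature_matrix()]; the standard entry
#' point for parameter-recovery studies.
#'
#' @param cfg a [sim_config()]
#' @param engine thermodynamics engine for the featurizer
#' @param dataset dataset label
#' @return list: `sim`, `guides`, `observations`, `truth`, `features`
#'   (a `feature_matrix`), `X`, `Z`, `cluster`, `y`
#' @export
simulate_study <- function(cfg = sim_preset("default"),
                           engine = thermo_engine_nn(), dataset = "E75") {
  sim <- simulate_genome(cfg)
  guides <- simulate_guides(sim, cfg)
  scr <- simulate_screen(sim, guides, cfg, dataset = dataset)
  fm <- build_feature_matrix(guides, sim$genes, scr$observations,
                             engine = engine)
  list(sim = sim, guides = guides, observations = scr$observations,
       truth = scr$truth, features = fm,
       X = fm$fixed, Z = fm$random,
       cluster = scr$observations$gene_id, y = scr$observations$logfc)
}
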