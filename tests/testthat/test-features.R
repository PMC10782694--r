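test_that("feature registry has the canonical composition", {
  reg <- feature_registry()
  expect_length(reg$fixed_names, 129L)
  expect_length(reg$random_names, 9L)
  expect_length(unique(c(reg$fixed_names, reg$random_names)), 138L)
  # 120 one-hot columns, 4 per context position
  onehot <- grep("^(-[1-4]|G[0-9]+|P[1-3]|\\+[1-3])_[ACGT]$", reg$fixed_names)
  expect_length(onehot, 120L)
  expect_length(reg$context_labels, 30L)
})

test_that("one-hot encoding follows the index formula and is invertible", {
  v <- one_hot_context(strrep("A", 30))
  expect_length(v, 120L)
  expect_equal(sum(v), 30)
  expect_true(all(which(v == 1) == 4 * (0:29) + 1))  # all A channels

  # cyclic input walks the channels: index 4*pos + channel (0-based oracle)
  ctx <- substr(strrep("ACGT", 8), 1, 30)
  v2 <- one_hot_context(ctx)
  expected_idx <- 4 * (0:29) + (rep(0:3, length.out = 30)) + 1
  expect_equal(unname(which(v2 == 1)), expected_idx)
  expect_equal(decode_one_hot(v2), ctx)

  # every 4-block sums to one for random valid inputs
  set.seed(11)
  for (i in 1:20) {
    ctx <- random_dna(30)
    v <- one_hot_context(ctx)
    expect_true(all(colSums(matrix(v, nrow = 4)) == 1))
    expect_equal(decode_one_hot(v), ctx)
  }

  expect_error(one_hot_context("ACGT"), "length 30")
  expect_error(one_hot_context(paste0(strrep("A", 29), "N")), "position 30")
})

test_that("homopolymer equals a brute-force run scan", {
  expect_equal(homopolymer("ACGTACGTACGTACGTACGT"), 1L)
  expect_equal(homopolymer("AAAAACGTACGTACGTACGT"), 5L)
  set.seed(21)
  for (i in 1:200) {
    s <- random_dna(20)
    ch <- strsplit(s, "")[[1]]
    best <- 1L; run <- 1L
    for (j in 2:20) {
      run <- if (ch[j] == ch[j - 1L]) run + 1L else 1L
      best <- max(best, run)
    }
    expect_equal(homopolymer(s), best)
  }
  # bounds: 1 <= h <= len, equality iff single-nucleotide repeat
  expect_equal(homopolymer(strrep("G", 20)), 20L)
})

test_that("CAI is the geometric mean of relative adaptiveness", {
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  w1 <- stats::setNames(rep(1, length(sense)), sense)
  expect_equal(compute_cai("ATGGCTGCAACC", w1), 1.0)

  # single repeated codon with weight w -> CAI == w
  w <- w1; w["GCT"] <- 0.4
  expect_equal(compute_cai(strrep("GCT", 10), w), 0.4)

  # 30-codon toy CDS vs independent log-domain oracle
  set.seed(31)
  wr <- stats::setNames(runif(length(sense), 0.05, 1), sense)
  for (aa in unique(gc[sense])) wr[gc[sense] == aa][1] <- 1
  cds <- paste(sample(sense, 30, replace = TRUE), collapse = "")
  codons <- substring(cds, seq(1, 88, 3), seq(3, 90, 3))
  aa <- gc[codons]
  single <- names(table(gc[sense]))[table(gc[sense]) == 1]
  keep <- aa != "*" & !(aa %in% single)
  oracle <- exp(sum(log(wr[codons[keep]])) / sum(keep))
  expect_equal(compute_cai(cds, wr), oracle, tolerance = 1e-12)

  expect_error(compute_cai("ATGGC", w1), "divisible")
})

test_that("gene feature vector summarizes expression under the OD cap", {
  g <- gene_annotation("x", strrep("ACG", 50), 1, 150,
                       expression_by_od = c("0.5" = 5, "1.0" = 5, "2.0" = 5))
  v <- gene_feature_vector(g, "E75")
  expect_equal(unname(v[c("expr_min", "expr_max")]), c(5, 5))
  expect_equal(names(v), feature_registry()$random_names)

  g2 <- gene_annotation("y", strrep("ACG", 50), 1, 150,
                        expression_by_od = c("0.5" = 3, "1.0" = 9, "2.0" = 1))
  v2 <- gene_feature_vector(g2, "Wang", od_cap = 0.6)
  expect_equal(unname(v2["expr_min"]), 3)
  expect_equal(unname(v2["expr_max"]), 3)
  expect_error(gene_feature_vector(g2, "Wang", od_cap = 0.1), "od_cap")

  # treatment coding against the reference dataset
  expect_equal(unname(gene_feature_vector(g, "E75")[8:9]), c(0, 0))
  expect_equal(unname(gene_feature_vector(g, "E18")[8:9]), c(1, 0))
  expect_equal(unname(gene_feature_vector(g, "Wang")[8:9]), c(0, 1))
})

test_that("guide enumeration equals a brute-force window scan", {
  # property over seeded toy genes, no filters
  for (seed in 1:25) {
    toy <- make_toy_gene(len = 120L, seed = seed)
    sites <- enumerate_guides(toy$gene, toy$ctx, cds_offset = 30L,
                              gc_min = 0, gc_max = 1,
                              forbidden_motifs = character())
    oracle <- brute_force_scan(toy$ctx, toy$cds_start, toy$cds_end)
    expect_equal(sites$dist_start_codon, oracle)
  }
  # and with the default GC / BbsI filters active
  for (seed in 26:50) {
    toy <- make_toy_gene(len = 150L, seed = seed)
    sites <- suppressMessages(enumerate_guides(toy$gene, toy$ctx,
                                               cds_offset = 30L))
    oracle <- brute_force_scan(toy$ctx, toy$cds_start, toy$cds_end,
                               gc_min = 0.30, gc_max = 0.85,
                               forbidden = c("GAAGAC", "GTCTTC"))
    expect_equal(sites$dist_start_codon, oracle)
  }
})

test_that("enumerated guides satisfy the context layout invariants", {
  toy <- make_toy_gene(len = 150L, seed = 99L)
  sites <- enumerate_guides(toy$gene, toy$ctx, cds_offset = 30L,
                            gc_min = 0, gc_max = 1,
                            forbidden_motifs = character())
  expect_gt(nrow(sites), 0L)
  expect_true(all(substr(sites$context30, 26, 27) == "GG"))   # P2 P3
  expect_true(all(substr(sites$context30, 5, 24) == sites$spacer))
  expect_true(all(grepl("GG$", sites$pam)))
  expect_true(all(diff(sites$dist_start_codon) >= 0))          # sorted
  expect_equal(sites$rel_dist, sites$dist_start_codon / 150)
})

test_that("enumeration applies GC bounds inclusively and motif filters", {
  # hand-built gene: spacer with GC 0.25 must be excluded
  # sense 20-mer = revcomp(spacer); build context = flank CC sense20 flank
  spacer_lowgc <- "AAAATAAATAAATAAATGCG"  # GC 4/20 = 0.20 < 0.30
  sense <- revcomp(spacer_lowgc)
  ctx <- paste0("AAAAAAA", "CCA", sense, "AAAAAAA")
  cds_start <- 8L
  gene <- gene_annotation("low", substr(ctx, cds_start, nchar(ctx) - 7L),
                          cds_start, nchar(ctx) - 7L)
  sites <- enumerate_guides(gene, ctx, cds_offset = cds_start - 1L)
  expect_false(spacer_lowgc %in% sites$spacer)
  sites_nofilter <- enumerate_guides(gene, ctx, cds_offset = cds_start - 1L,
                                     gc_min = 0, gc_max = 1)
  expect_true(spacer_lowgc %in% sites_nofilter$spacer)

  # BbsI site on either strand excludes the guide
  spacer_bbsi <- "ACGTGAAGACGTACGTACGT"
  sense2 <- revcomp(spacer_bbsi)
  ctx2 <- paste0("AAAAAAA", "CCA", sense2, "AAAAAAA")
  gene2 <- gene_annotation("bbsi", substr(ctx2, 8L, nchar(ctx2) - 7L),
                           8L, nchar(ctx2) - 7L)
  s2 <- enumerate_guides(gene2, ctx2, cds_offset = 7L, gc_min = 0, gc_max = 1)
  expect_false(spacer_bbsi %in% s2$spacer)

  # non-ACGT characters reject the gene outright
  expect_error(enumerate_guides(gene2, sub("A", "N", ctx2)), "non-ACGT")
})

test_that("sites with too-short flanks are skipped with a notice", {
  # CC at the very first position: the 30-nt context would need 3 nt of
  # upstream flank that is not available
  set.seed(7)
  ctx <- paste0("CC", random_dna(120))
  gene <- gene_annotation("flanky", ctx, 1L, nchar(ctx))
  expect_message(
    enumerate_guides(gene, ctx, cds_offset = 0L,
                     gc_min = 0, gc_max = 1, forbidden_motifs = character()),
    "flank too short")
})

test_that("distance features follow the coordinate arithmetic", {
  gene <- gene_annotation("d", strrep("ACT", 100), 501, 800,
                          tu_id = "TU1", index_in_tu = 0L, tu_offset = 120L)
  site <- list(dist_start_codon = 150L)
  df <- distance_features(site, gene)
  expect_equal(df$rel_dist, 0.5)
  expect_equal(df$dist_tu_start, 270L)       # offset + gene-to-TU distance
  expect_true(df$targets_first_gene)
  df0 <- distance_features(list(dist_start_codon = 0L), gene)
  expect_equal(df0$rel_dist, 0)
  expect_equal(df0$dist_tu_start, 120L)
  expect_error(distance_features(list(dist_start_codon = 300L), gene),
               "outside")
  gene2 <- gene_annotation("d2", strrep("ACT", 100), 1, 300, index_in_tu = 1L)
  expect_false(distance_features(site, gene2)$targets_first_gene)
})

test_that("feature matrix has registry dimensions and standardized gene block", {
  toy <- make_toy_gene(len = 300L, seed = 5L,
                       expression_by_od = c("0.4" = 2, "0.8" = 8))
  sites <- enumerate_guides(toy$gene, toy$ctx, cds_offset = 30L,
                            gc_min = 0, gc_max = 1,
                            forbidden_motifs = character())
  obs <- data.frame(guide_id = sites$guide_id, gene_id = toy$gene$gene_id,
                    dataset = "E75")
  fm <- build_feature_matrix(sites, stats::setNames(list(toy$gene),
                                                    toy$gene$gene_id),
                             obs, engine = thermo_engine_const(-1))
  expect_equal(dim(fm$fixed), c(nrow(sites), 129L))
  expect_equal(dim(fm$random), c(nrow(sites), 9L))
  expect_equal(colnames(fm$fixed), feature_registry()$fixed_names)
  # single observation keeps its shape
  fm1 <- build_feature_matrix(sites, stats::setNames(list(toy$gene),
                                                     toy$gene$gene_id),
                              obs[1, , drop = FALSE],
                              engine = thermo_engine_const(-1))
  expect_equal(dim(fm1$fixed), c(1L, 129L))
  expect_error(build_feature_matrix(sites, list(), obs,
                                    engine = thermo_engine_const(-1)),
               "missing gene")
})

test_that("random block standardization is population mean-0 sd-1", {
  st <- simulate_study(sim_config(n_genes = 20L, guides_per_gene = 5L,
                                  seed = 12L),
                       engine = thermo_engine_const(-1))
  Z <- st$Z
  nonconst <- apply(st$features$random_raw, 2, function(x) sd(x) > 0)
  expect_true(all(abs(colMeans(Z)) < 1e-9))
  popsd <- sqrt(colMeans(sweep(Z, 2, colMeans(Z))^2))
  expect_true(all(abs(popsd[nonconst] - 1) < 1e-9))
  expect_true(all(Z[, !nonconst] == 0))
})
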