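# Shared fixtures and independent oracles used across the test files.
# Oracles deliberately re-derive quantities by brute force / closed form,
# independently of the package implementation.

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# brute-force coding-strand guide scan: count/locate CC placements whose
# 20-nt protospacer lies inside the CDS and whose 30-nt context fits in the
# available sequence; returns 0-based distances of G1 from the start codon
brute_force_scan <- function(ctx, cds_start, cds_end,
                             gc_min = 0, gc_max = 1,
                             forbidden = character()) {
  chars <- strsplit(ctx, "")[[1]]
  res <- integer(0)
  for (c0 in seq_len(nchar(ctx) - 1L)) {
    if (chars[c0] != "C" || chars[c0 + 1L] != "C") next
    if (c0 + 3L < cds_start || c0 + 22L > cds_end) next
    if (c0 - 3L < 1L || c0 + 26L > nchar(ctx)) next
    sense20 <- substr(ctx, c0 + 3L, c0 + 22L)
    spacer <- revcomp(sense20)
    gc <- (nchar(spacer) - nchar(gsub("[GC]", "", spacer))) / nchar(spacer)
    if (gc < gc_min || gc > gc_max) next
    if (length(forbidden)) {
      both <- c(forbidden, revcomp(forbidden))
      if (any(vapply(both, function(m) grepl(m, spacer, fixed = TRUE),
                     logical(1)))) next
    }
    res <- c(res, c0 + 22L - cds_start)
  }
  sort(res)
}

# toy annotated gene embedded in random flanks
make_toy_gene <- function(len = 120L, flank = 30L, seed = 1L, ...) {
  set.seed(seed)
  ctx <- random_dna(len + 2L * flank)
  cds <- substr(ctx, flank + 1L, flank + len)
  gene <- gene_annotation(paste0("g", seed), cds, flank + 1L, flank + len, ...)
  list(gene = gene, ctx = ctx, cds_start = flank + 1L, cds_end = flank + len)
}

# small deterministic fitted forest for attribution tests
small_forest_fit <- function(n = 250L, p = 5L, seed = 3L, num.trees = 50L,
                             max_depth = 4L, interaction = FALSE) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n)
  colnames(X) <- paste0("f", seq_len(p))
  y <- 2 * X[, 1] + (if (interaction) X[, 2] * X[, 3] else X[, 2]) +
    rnorm(n, 0, 0.3)
  g <- rep(seq_len(n %/% 5L), length.out = n)
  merf(X, NULL, g, y,
       hp = merf_hyperparams(n_estimators = num.trees, max_depth = max_depth,
                             min_samples_leaf = 3L),
       max_iter = 2L, seed = seed)
}

# path-dependent conditional expectation of an extracted tree (oracle)
oracle_expvalue <- function(tree, x, S, j = 1L) {
  if (tree$terminal[j]) return(tree$value[j])
  f <- tree$feat[j]
  if (f %in% S) {
    nx <- if (x[f] <= tree$thr[j]) tree$left[j] else tree$right[j]
    oracle_expvalue(tree, x, S, nx)
  } else {
    (tree$cover[tree$left[j]] * oracle_expvalue(tree, x, S, tree$left[j]) +
       tree$cover[tree$right[j]] * oracle_expvalue(tree, x, S, tree$right[j])) /
      tree$cover[j]
  }
}

# exhaustive Shapley values of one tree over the subset lattice (oracle)
oracle_tree_shapley <- function(tree, x, p) {
  feats <- sort(unique(tree$feat[!tree$terminal]))
  M <- length(feats)
  phi <- numeric(p)
  subsets <- function(v) {
    if (!length(v)) return(list(integer(0)))
    rest <- subsets(v[-1])
    c(rest, lapply(rest, function(s) c(v[1], s)))
  }
  for (i in feats) {
    for (S in subsets(setdiff(feats, i))) {
      w <- factorial(length(S)) * factorial(M - length(S) - 1L) / factorial(M)
      phi[i] <- phi[i] +
        w * (oracle_expvalue(tree, x, c(S, i)) - oracle_expvalue(tree, x, S))
    }
  }
  phi
}
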