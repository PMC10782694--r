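test_that("extracted trees reproduce the forest predictions exactly", {
  fit <- small_forest_fit()
  fo <- crisprimerf:::extract_forest(fit$forest$rf, fit$X_train)
  X <- fit$X_train[1:30, ]
  expect_equal(crisprimerf:::predict_extracted(fo, X),
               crisprimerf:::predict_fixed_learner(fit$forest, X),
               tolerance = 1e-12)
})

test_that("tree attributions equal brute-force Shapley over the subset lattice", {
  fit <- small_forest_fit(interaction = TRUE)
  fo <- crisprimerf:::extract_forest(fit$forest$rf, fit$X_train)
  for (t in 1:4) {
    tree <- fo$trees[[t]]
    for (i in c(1L, 7L, 19L)) {
      x <- fit$X_train[i, ]
      expect_equal(crisprimerf:::treeshap_one(tree, x, 5L),
                   oracle_tree_shapley(tree, x, 5L), tolerance = 1e-9)
    }
  }
})

test_that("exact attributions satisfy local accuracy on 100 rows", {
  fit <- small_forest_fit(interaction = TRUE, n = 300L)
  at <- attribute(fit, fit$X_train[1:100, ], method = "exact_tree")
  err <- abs(at$base_value + rowSums(at$values) - at$prediction)
  expect_lt(max(err), 1e-6)
  # deterministic
  at2 <- attribute(fit, fit$X_train[1:5, ], method = "exact_tree")
  expect_equal(at$values[1:5, ], at2$values)
})

test_that("permutation attributions also satisfy local accuracy", {
  fit <- small_forest_fit()
  at <- attribute(fit, fit$X_train[1:5, ], method = "permutation",
                  background = fit$X_train[1:40, ], nperm = 8L, seed = 2)
  err <- abs(at$base_value + rowSums(at$values) - at$prediction)
  expect_lt(max(err), 1e-9)
})

test_that("features unused by every tree receive exactly zero attribution", {
  set.seed(81)
  n <- 300L
  X <- cbind(signal = rnorm(n), dead1 = rnorm(n), dead2 = rnorm(n))
  y <- 3 * X[, "signal"]           # only one informative feature
  fit <- merf(X, NULL, rep(1:30, each = 10), y,
              hp = merf_hyperparams(n_estimators = 50L, max_depth = 3L,
                                    max_features = 1),
              max_iter = 2L, seed = 5, fix_D = matrix(0, 1, 1))
  fo <- crisprimerf:::extract_forest(fit$forest$rf, fit$X_train)
  used <- unique(unlist(lapply(fo$trees, function(t) t$feat[!t$terminal])))
  at <- attribute(fit, X[1:20, ], method = "exact_tree")
  unused <- setdiff(1:3, used)
  if (length(unused))
    expect_true(all(at$values[, unused] == 0))
  expect_gt(mean(abs(at$values[, "signal"])), 0)
})

test_that("constant models attribute nothing", {
  set.seed(82)
  X <- matrix(rnorm(100), 50)
  colnames(X) <- c("a", "b")
  fit <- merf(X, NULL, rep(1:5, 10), rep(2.5, 50), max_iter = 2L, seed = 1,
              fixed_learner = "mean", fix_D = matrix(0, 1, 1))
  at <- attribute(fit, X[1:10, ])
  expect_true(all(at$values == 0))
  expect_equal(at$base_value, 2.5)
})

test_that("mean absolute importance ranks features by attribution magnitude", {
  at <- structure(list(values = cbind(a = c(0, 0, 0), b = c(1, -2, 3),
                                      c = c(0.1, 0.1, -0.1)),
                       base_value = 0, feature_names = c("a", "b", "c"),
                       prediction = c(1.1, -1.9, 2.9)),
                  class = "attribution")
  imp <- mean_abs_importance(at)
  expect_equal(imp$feature, c("b", "c", "a"))
  expect_equal(imp$importance, c(2, 0.1, 0))
  # all-zero matrix -> all zeros
  at0 <- at; at0$values[] <- 0
  expect_true(all(mean_abs_importance(at0)$importance == 0))
})

test_that("interaction table is additive-null, detects XOR, flags strata", {
  # purely additive attributions: deviation 0 for +/+ and -/-
  p1 <- rep(c(TRUE, FALSE), each = 8)
  p2 <- rep(c(TRUE, FALSE), times = 8)
  a1 <- ifelse(p1, 2, -1)                     # depends only on own presence
  a2 <- ifelse(p2, 0.5, -0.25)
  tab <- interaction_combination_table(a1, a2, p1, p2)
  expect_equal(tab$deviation[tab$combination == "+/+"], 0, tolerance = 1e-9)
  expect_equal(tab$deviation[tab$combination == "-/-"], 0, tolerance = 1e-9)

  # XOR-style: each feature's attribution flips sign with partner presence
  p1x <- c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE)
  p2x <- c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE)
  a1x <- ifelse(p1x & p2x, -2, ifelse(p1x, 1, 0))
  a2x <- ifelse(p1x & p2x, -2, ifelse(p2x, 1, 0))
  tabx <- interaction_combination_table(a1x, a2x, p1x, p2x)
  expect_gt(abs(tabx$deviation[tabx$combination == "+/+"]), 0)

  # symmetric under swapping the features
  tab_sw <- interaction_combination_table(a2x, a1x, p2x, p1x)
  expect_equal(tab_sw$deviation[tab_sw$combination == "+/+"],
               tabx$deviation[tabx$combination == "+/+"])

  # all samples +/+ -> the other strata are flagged missing
  tab_all <- interaction_combination_table(a1x[1], a2x[1], TRUE, TRUE)
  expect_true(all(tab_all$missing[tab_all$combination != "+/+"]))
  expect_false(tab_all$missing[tab_all$combination == "+/+"])
})

test_that("interaction pair ranking surfaces the strongest deviation", {
  set.seed(83)
  n <- 120L
  pres <- cbind(u = runif(n) < 0.5, v = runif(n) < 0.5, w = runif(n) < 0.5)
  # u and v interact; w is additive
  au <- ifelse(pres[, "u"] & pres[, "v"], -3, ifelse(pres[, "u"], 1, 0))
  av <- ifelse(pres[, "u"] & pres[, "v"], -3, ifelse(pres[, "v"], 1, 0))
  aw <- ifelse(pres[, "w"], 0.5, -0.5)
  at <- structure(list(values = cbind(u = au, v = av, w = aw),
                       base_value = 0, feature_names = c("u", "v", "w"),
                       prediction = au + av + aw),
                  class = "attribution")
  ranked <- rank_interaction_pairs(at, pres, min_n = 3L)
  expect_setequal(c(ranked$feature_1[1], ranked$feature_2[1]), c("u", "v"))
})

test_that("distance profile separates the sensitive window when present", {
  set.seed(84)
  n <- 200L
  dist <- sample(0:500, n, replace = TRUE)
  # attribution pushed negative (stronger depletion) inside 60 nt
  v <- ifelse(dist < 60, -0.8, 0.1) + rnorm(n, 0, 0.05)
  at <- structure(list(values = matrix(v, ncol = 1,
                                       dimnames = list(NULL,
                                                       "dist_start_codon")),
                       base_value = 0, feature_names = "dist_start_codon",
                       prediction = v),
                  class = "attribution")
  prof <- distance_effect_profile(at, dist)
  expect_lt(prof$inside_mean, prof$outside_mean)
  expect_lt(prof$difference, 0)

  # attribution independent of distance: difference ~ 0
  v2 <- rnorm(n, 0, 0.05)
  at2 <- at; at2$values[, 1] <- v2; at2$prediction <- v2
  prof2 <- distance_effect_profile(at2, dist)
  expect_lt(abs(prof2$difference), 0.05)

  # empty stratum is flagged
  prof3 <- distance_effect_profile(at, rep(100L, n))
  expect_true(prof3$missing_stratum)

  # first-gene stratification returns the 2x2 cell means
  fg <- rep(c(TRUE, FALSE), n / 2)
  prof4 <- distance_effect_profile(at, dist, first_gene = fg)
  expect_equal(nrow(prof4$by_first_gene), 4L)
})
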