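test_that("BLUPs match the scalar Woodbury formula and its limits", {
  set.seed(61)
  # intercept-only, scalar d: b = d * n * rbar / (d * n + sigma2)
  for (i in 1:20) {
    d <- runif(1, 0.1, 5); s2 <- runif(1, 0.1, 2); ni <- sample(3:12, 1)
    r <- rnorm(ni)
    b <- estep_blups(matrix(d, 1, 1), s2, matrix(1, ni, 1), r)
    expect_equal(b, d * ni * mean(r) / (d * ni + s2), tolerance = 1e-12)
  }
  # D = 0 -> b = 0
  expect_equal(estep_blups(matrix(0, 1, 1), 1, matrix(1, 5, 1), rnorm(5)), 0)
  # sigma2 -> 0 with full-rank Z: Z b approaches the residual projection
  Zi <- cbind(1, rnorm(4), rnorm(4), rnorm(4))
  r <- rnorm(4)
  b <- estep_blups(diag(4), 1e-10, Zi, r)
  expect_equal(drop(Zi %*% b), r, tolerance = 1e-6)
  expect_error(estep_blups(diag(2), 1, matrix(1, 5, 1), rnorm(5)), "dimension")
})

test_that("EM with constant fixed effect recovers one-way variance components", {
  set.seed(62)
  m <- 60L; ncl <- 8L
  u <- rnorm(m, 0, sqrt(3))
  y <- 5 + rep(u, each = ncl) + rnorm(m * ncl)
  g <- rep(seq_len(m), each = ncl)
  X <- matrix(0, m * ncl, 1, dimnames = list(NULL, "unused"))
  fit <- merf(X, NULL, g, y, max_iter = 200L, tol = 1e-8, seed = 1,
              fixed_learner = "mean")
  # method-of-moments oracle for the balanced one-way random-intercept model
  ybar <- tapply(y, g, mean)
  MSW <- sum((y - ybar[as.character(g)])^2) / (m * ncl - m)
  MSB <- ncl * sum((ybar - mean(y))^2) / (m - 1)
  d_mom <- (MSB - MSW) / ncl
  expect_lt(abs(fit$sigma2 - MSW) / MSW, 0.05)
  expect_lt(abs(fit$D[1, 1] - d_mom) / d_mom, 0.05)
  expect_true(fit$converged)
})

test_that("pinning D at zero reduces the model to a plain seeded forest", {
  set.seed(63)
  n <- 200L; p <- 5L
  X <- matrix(rnorm(n * p), n); colnames(X) <- paste0("f", 1:p)
  y <- X[, 1] + rnorm(n, 0, 0.5)
  g <- rep(1:20, each = 10)
  hp <- merf_hyperparams(n_estimators = 100L, max_depth = 6L)
  fit <- merf(X, NULL, g, y, hp = hp, max_iter = 4L, seed = 42,
              fix_D = matrix(0, 1, 1))
  expect_true(all(fit$b == 0))
  plain <- crisprimerf:::fit_fixed_learner(X, y, hp, 42)
  expect_equal(predict(fit, X),
               crisprimerf:::predict_fixed_learner(plain, X))
})

test_that("fixed-effect prediction ignores gene features and cluster ids", {
  fit <- small_forest_fit()
  X <- fit$X_train[1:20, ]
  p1 <- predict(fit, X, type = "fixed")
  p2 <- predict(fit, X, Z = NULL, cluster = rep("unknown", 20), type = "full")
  expect_message(
    p2 <- predict(fit, X, Z = NULL, cluster = rep("unknown", 20),
                  type = "full"),
    "unseen")
  expect_equal(p1, p2)  # unseen cluster: fixed effect only
  expect_error(predict(fit, X[, 1:3]), "columns")
})

test_that("a depth-1 single tree is evaluated exactly as hand-traced", {
  # construct a split at f1 <= 0 by giving ranger a perfectly separable y
  X <- matrix(c(rep(-1, 50), rep(1, 50)), ncol = 1,
              dimnames = list(NULL, "f1"))
  y <- c(rep(0, 50), rep(10, 50))
  fit <- merf(X, NULL, rep(1:10, 10), y,
              hp = merf_hyperparams(n_estimators = 50L, max_depth = 2L,
                                    min_samples_leaf = 1L, bootstrap = FALSE),
              max_iter = 1L, seed = 1, fix_D = matrix(0, 1, 1))
  pred <- predict(fit, matrix(c(-2, 2), ncol = 1,
                              dimnames = list(NULL, "f1")))
  expect_equal(pred, c(0, 10))
})

test_that("full predictions beat fixed-only on clustered simulated data", {
  set.seed(64)
  n <- 300L
  X <- matrix(rnorm(n * 4), n); colnames(X) <- paste0("f", 1:4)
  g <- rep(1:30, each = 10)
  u <- rnorm(30, 0, 2)
  y <- X[, 1] + u[g] + rnorm(n, 0, 0.4)
  fit <- merf(X, NULL, g, y,
              hp = merf_hyperparams(n_estimators = 80L, max_depth = 6L),
              max_iter = 6L, seed = 9)
  pf <- predict(fit, X, type = "fixed")
  pfull <- predict(fit, X, Z = NULL, cluster = g, type = "full")
  expect_lt(stats::var(y - pfull), stats::var(y - pf))
  # clusters with b = 0 coincide with the fixed effect
  fit0 <- merf(X, NULL, g, y, hp = merf_hyperparams(n_estimators = 50L),
               max_iter = 2L, seed = 9, fix_D = matrix(0, 1, 1))
  expect_equal(predict(fit0, X, Z = NULL, cluster = g, type = "full"),
               predict(fit0, X, type = "fixed"))
})

test_that("GLL converges and D stays symmetric PSD across iterations", {
  set.seed(65)
  m <- 40L; ncl <- 6L
  Zg <- matrix(rnorm(m * 2), m)           # two cluster-level covariates
  B <- cbind(rnorm(m, 0, 1), rnorm(m, 0, 0.8), rnorm(m, 0, 0.5))
  g <- rep(seq_len(m), each = ncl)
  y <- rowSums(cbind(1, Zg)[g, ] * B[g, ]) + rnorm(m * ncl, 0, 0.8)
  Z <- Zg[g, ]
  X <- matrix(0, m * ncl, 1, dimnames = list(NULL, "unused"))
  fit <- merf(X, Z, g, y, max_iter = 300L, tol = 1e-3, seed = 2,
              fixed_learner = "mean")
  expect_true(fit$converged)
  expect_lt(length(fit$gll_trace), 300L)
  expect_equal(fit$D, t(fit$D))
  expect_gte(min(eigen(fit$D, symmetric = TRUE, only.values = TRUE)$values),
             -1e-8)
  expect_gt(fit$sigma2, 0)
  expect_equal(nrow(fit$b), m)
})

test_that("sigma2 is recovered when the true D is zero", {
  set.seed(66)
  n <- 3000L
  y <- rnorm(n, 0, sqrt(2))               # no cluster effect at all
  g <- rep(seq_len(300L), each = 10L)
  X <- matrix(0, n, 1, dimnames = list(NULL, "unused"))
  fit <- merf(X, NULL, g, y, max_iter = 60L, tol = 1e-6, seed = 3,
              fixed_learner = "mean")
  expect_lt(abs(fit$sigma2 - 2) / 2, 0.15)
})

test_that("hyperparameter search respects ranges and improves with budget", {
  # all sampled configurations stay in the stated space
  cfgs <- list()
  tuned <- tune_hyperparameters(function(hp) {
    cfgs[[length(cfgs) + 1L]] <<- hp
    -(hp$max_depth - 11)^2   # peak inside the range
  }, budget = 100L, seed = 4)
  for (hp in cfgs) {
    expect_true(hp$n_estimators %in% seq(50L, 1000L, 10L))
    expect_true(hp$max_features > 0 && hp$max_features <= 1)
    expect_true(hp$max_depth >= 2L && hp$max_depth <= 30L)
    expect_true(hp$min_samples_leaf >= 1L && hp$min_samples_leaf <= 20L)
    expect_true(hp$min_samples_split >= 2L && hp$min_samples_split <= 20L)
  }
  expect_s3_class(tuned, "merf_hyperparams")

  # best-of-20 >= best-of-1 for the same seed sequence
  obj <- function(hp) hp$max_features
  s1 <- attr(tune_hyperparameters(obj, budget = 1L, seed = 5), "trials")$score
  s20 <- attr(tune_hyperparameters(obj, budget = 20L, seed = 5), "trials")$score
  expect_gte(max(s20), max(s1))

  # failing objective is logged, not fatal
  expect_message(
    t2 <- tune_hyperparameters(function(hp)
      if (hp$max_depth > 5) stop("boom") else 1, budget = 10L, seed = 6),
    "failed")
  expect_s3_class(t2, "merf_hyperparams")
})
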