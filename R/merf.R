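#' Hyperparameters of the fixed-effect random forest
#'
#' Validated container for the forest hyperparameters.  Defaults are
#' mid-range values of the supported search space; [tune_hyperparameters()]
#' can replace them with a tuned configuration.
#'
#' @param bootstrap draw bootstrap samples per tree?
#' @param n_estimators number of trees, in \[50, 1000\]
#' @param max_features fraction of features tried per split, in (0, 1\]
#' @param max_depth maximum tree depth, in \[2, 30\]
#' @param min_samples_leaf minimal node size, in \[1, 20\]
#' @param min_samples_split minimal size to attempt a split, in \[2, 20\]
#'   (carried for compatibility; the forest backend controls node size via
#'   `min_samples_leaf` only)
#' @return list of class `merf_hyperparams`
#' @export
merf_hyperparams <- function(bootstrap = TRUE, n_estimators = 500L,
                             max_features = 0.3, max_depth = 15L,
                             min_samples_leaf = 5L, min_samples_split = 2L) {
  stopifnot(is.logical(bootstrap), length(bootstrap) == 1L,
            n_estimators >= 50L, n_estimators <= 1000L,
            max_features > 0, max_features <= 1,
            max_depth >= 2L, max_depth <= 30L,
            min_samples_leaf >= 1L, min_samples_leaf <= 20L,
            min_samples_split >= 2L, min_samples_split <= 20L)
  structure(list(bootstrap = bootstrap,
                 n_estimators = as.integer(n_estimators),
                 max_features = max_features,
                 max_depth = as.integer(max_depth),
                 min_samples_leaf = as.integer(min_samples_leaf),
                 min_samples_split = as.integer(min_samples_split)),
            class = "merf_hyperparams")
}

#' @export
print.merf_hyperparams <- function(x, ...) {
  cat("<merf_hyperparams> trees=", x$n_estimators, " depth<=", x$max_depth,
      " mtry_frac=", x$max_features, " leaf>=", x$min_samples_leaf,
      " bootstrap=", x$bootstrap, "\n", sep = "")
  invisible(x)
}

# Fit the fixed-effect learner.  learner = "mean" replaces the forest by the
# constant mean predictor (useful to reduce the EM to a linear mixed model).
fit_fixed_learner <- function(X, y, hp, seed, learner = "ranger") {
  if (learner == "mean")
    return(structure(list(type = "mean", value = mean(y)),
                     class = "merf_learner"))
  rf <- ranger::ranger(
    x = X, y = y,
    num.trees = hp$n_estimators,
    mtry = max(1L, min(ncol(X), ceiling(hp$max_features * ncol(X)))),
    max.depth = hp$max_depth,
    min.node.size = hp$min_samples_leaf,
    replace = hp$bootstrap,
    sample.fraction = 1,
    seed = seed, num.threads = 1L, oob.error = FALSE)
  structure(list(type = "ranger", rf = rf), class = "merf_learner")
}

predict_fixed_learner <- function(learner, X) {
  if (learner$type == "mean") return(rep(learner$value, nrow(X)))
  stats::predict(learner$rf, data = X, num.threads = 1L)$predictions
}

#' Best linear unbiased predictor of one cluster's random effects
#'
#' `b_i = D Z_i' (Z_i D Z_i' + sigma2 I)^-1 r_i`, the E-step estimate of the
#' cluster coefficients given the current variance components.
#'
#' @param D q x q random-effect covariance (PSD)
#' @param sigma2 residual variance (> 0)
#' @param Z_i cluster random-effect design, n_i x q
#' @param resid_i residuals `y_i - f(X_i)`, length n_i
#' @return numeric vector of length q
#' @export
estep_blups <- function(D, sigma2, Z_i, resid_i) {
  Z_i <- as.matrix(Z_i)
  if (ncol(Z_i) != nrow(D) || nrow(D) != ncol(D) || nrow(Z_i) != length(resid_i))
    stop("dimension mismatch between D, Z_i and resid_i", call. = FALSE)
  if (sigma2 <= 0) stop("sigma2 must be > 0", call. = FALSE)
  V <- Z_i %*% D %*% t(Z_i) + diag(sigma2, nrow(Z_i))
  drop(D %*% t(Z_i) %*% solve(V, resid_i))
}

#' Fit a mixed-effect random forest by expectation-maximization
#'
#' Models a depletion measurement as `y = f(X) + Z b_cluster + eps`, with a
#' random forest `f` over guide features (fixed effects) and per-cluster
#' linear coefficients `b` over gene/dataset features (random effects,
#' `b ~ N(0, D)`, `eps ~ N(0, sigma2)`).  Clusters are genes: the random
#' intercept absorbs the per-gene depletion scale, so screens can be fused
#' without explicit normalization, and `f` alone scores guide efficiency.
#'
#' Each EM iteration (1) refits the forest to `y - Z b` with a fixed seed,
#' (2) recomputes the BLUPs `b_i = D Z_i' V_i^-1 (y_i - f(X_i))` with
#' `V_i = Z_i D Z_i' + sigma2 I`, and (3) updates `sigma2` and `D` from the
#' within-cluster residuals; iteration stops when the relative change in the
#' generalized log-likelihood (GLL) criterion falls below `tol`.
#'
#' @param X n x p fixed-effect (guide) feature matrix
#' @param Z n x k random-effect (gene/dataset) design; a leading intercept
#'   column is added when `intercept = TRUE` (so q = k + 1)
#' @param cluster length-n cluster labels (gene ids)
#' @param y length-n response (depletion logFC)
#' @param hp forest hyperparameters, see [merf_hyperparams()]
#' @param max_iter maximum EM iterations
#' @param tol relative GLL-change convergence tolerance
#' @param seed integer seed reused for every forest refit, making the fit
#'   deterministic given (data, hp, seed)
#' @param intercept prepend a random-intercept column to `Z`?
#' @param fixed_learner `"ranger"` (random forest) or `"mean"` (constant
#'   mean predictor, reducing the model to a linear mixed model)
#' @param fix_D optional q x q matrix: hold the random-effect covariance
#'   fixed at this value (e.g., a zero matrix pins all BLUPs at 0 and the
#'   fit degenerates to a plain forest on `y`)
#' @param verbose print the GLL per iteration?
#' @return object of class `merf`; see [predict.merf()], [summary.merf()],
#'   [coef.merf()]
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(400), 100, 4); colnames(X) <- paste0("f", 1:4)
#' g <- rep(1:10, each = 10)
#' y <- X[, 1] + rnorm(10)[g] + rnorm(100, 0, 0.3)
#' fit <- merf(X, Z = NULL, cluster = g, y = y,
#'             hp = merf_hyperparams(n_estimators = 50), max_iter = 5, seed = 1)
#' head(predict(fit, X))
#' @export
merf <- function(X, Z = NULL, cluster, y, hp = merf_hyperparams(),
                 max_iter = 50L, tol = 1e-3, seed = 1L, intercept = TRUE,
                 fixed_learner = c("ranger", "mean"), fix_D = NULL,
                 verbose = FALSE) {
  fixed_learner <- match.arg(fixed_learner)
  X <- as.matrix(X)
  n <- nrow(X)
  if (length(y) != n || length(cluster) != n)
    stop("X, y and cluster must agree in length", call. = FALSE)
  if (any(!is.finite(y))) stop("non-finite values in y", call. = FALSE)
  if (!is.null(Z)) {
    Z <- as.matrix(Z)
    stopifnot(nrow(Z) == n)
  }
  Zf <- if (intercept) cbind(`(Intercept)` = rep(1, n), Z) else Z
  if (is.null(Zf)) stop("need an intercept or a Z matrix", call. = FALSE)
  q <- ncol(Zf)
  cluster <- as.character(cluster)
  idx <- split(seq_len(n), cluster)
  m <- length(idx)
  clusters <- names(idx)

  D <- if (!is.null(fix_D)) {
    fix_D <- as.matrix(fix_D)
    stopifnot(nrow(fix_D) == q, ncol(fix_D) == q)
    fix_D
  } else diag(q)
  sigma2 <- 1
  b <- matrix(0, m, q, dimnames = list(clusters, colnames(Zf)))
  gll_trace <- numeric(0)
  converged <- FALSE
  jittered <- FALSE
  learner <- NULL

  for (iter in seq_len(max_iter)) {
    # (1) remove current cluster effects, refit the fixed learner
    zb <- rowSums(Zf * b[cluster, , drop = FALSE])
    ystar <- y - zb
    learner <- fit_fixed_learner(X, ystar, hp, seed, fixed_learner)
    fhat <- predict_fixed_learner(learner, X)
    r <- y - fhat

    # (2) E-step BLUPs and (3) M-step variance components
    sig_acc <- 0
    D_acc <- matrix(0, q, q)
    eps_list <- vector("list", m)
    for (i in seq_len(m)) {
      ii <- idx[[i]]
      Zi <- Zf[ii, , drop = FALSE]
      ri <- r[ii]
      ni <- length(ii)
      Vi <- Zi %*% D %*% t(Zi) + diag(sigma2, ni)
      Vinv <- solve(Vi)
      DZt <- D %*% t(Zi)
      bi <- drop(DZt %*% Vinv %*% ri)
      b[i, ] <- bi
      eps <- ri - drop(Zi %*% bi)
      eps_list[[i]] <- eps
      sig_acc <- sig_acc +
        sum(eps^2) + sigma2 * (ni - sigma2 * sum(diag(Vinv)))
      D_acc <- D_acc + tcrossprod(bi) + (D - DZt %*% Vinv %*% t(DZt))
    }
    sigma2 <- max(sig_acc / n, .Machine$double.eps)
    if (is.null(fix_D)) {
      D <- (D_acc + t(D_acc)) / (2 * m)
      ev <- eigen(D, symmetric = TRUE)
      if (min(ev$values) < 0)   # numerical guard: project back onto PSD cone
        D <- ev$vectors %*% diag(pmax(ev$values, 0), q) %*% t(ev$vectors)
    }

    # (4) generalized log-likelihood with the updated components
    Duse <- D
    if (!all(is.finite(determinant(Duse)$modulus)) ||
        determinant(Duse)$modulus[1] == -Inf ||
        min(eigen(Duse, symmetric = TRUE, only.values = TRUE)$values) < 1e-10) {
      Duse <- D + diag(1e-8, q)
      if (!jittered) {
        message("near-singular D: adding 1e-8 ridge for the GLL terms")
        jittered <- TRUE
      }
    }
    Dinv <- solve(Duse)
    logdetD <- as.numeric(determinant(Duse)$modulus)
    gll <- 0
    for (i in seq_len(m)) {
      ni <- length(idx[[i]])
      gll <- gll + sum(eps_list[[i]]^2) / sigma2 +
        drop(t(b[i, ]) %*% Dinv %*% b[i, ]) + logdetD + ni * log(sigma2)
    }
    gll_trace <- c(gll_trace, gll)
    if (verbose)
      message(sprintf("iter %d: GLL %.6g sigma2 %.4g", iter, gll, sigma2))
    if (iter >= 2L) {
      prev <- gll_trace[iter - 1L]
      if (abs(gll - prev) < tol * (abs(prev) + .Machine$double.eps)) {
        converged <- TRUE
        break
      }
    }
  }

  structure(list(forest = learner, D = D, sigma2 = sigma2, b = b,
                 gll_trace = gll_trace, converged = converged,
                 hp = hp, seed = seed, intercept = intercept,
                 q = q, clusters = clusters,
                 feature_names = colnames(X), X_train = X,
                 n = n, call = match.call()),
            class = "merf")
}

#' Predict from a fitted mixed-effect forest
#'
#' `type = "fixed"` (default) returns the fixed-effect forest prediction
#' only: the guide-efficiency score, independent of gene features or cluster
#' identity.  `type = "full"` adds the cluster random effect `Z b_cluster`;
#' clusters unseen in training contribute 0 (with a notice).
#'
#' @param object a fitted [merf()]
#' @param X fixed-effect feature matrix (columns as in training)
#' @param Z random-effect design (required for `type = "full"` when the
#'   model has gene features beyond the intercept)
#' @param cluster cluster labels (required for `type = "full"`)
#' @param type `"fixed"` or `"full"`
#' @param ... unused
#' @return numeric predictions
#' @export
predict.merf <- function(object, X, Z = NULL, cluster = NULL,
                         type = c("fixed", "full"), ...) {
  type <- match.arg(type)
  X <- as.matrix(X)
  if (!is.null(object$feature_names)) {
    if (ncol(X) != length(object$feature_names))
      stop("X has ", ncol(X), " columns; model expects ",
           length(object$feature_names), call. = FALSE)
    if (!is.null(colnames(X))) X <- X[, object$feature_names, drop = FALSE]
    else colnames(X) <- object$feature_names
  }
  fixed <- predict_fixed_learner(object$forest, X)
  if (type == "fixed") return(fixed)
  if (is.null(cluster)) stop("type = 'full' needs cluster labels", call. = FALSE)
  Zf <- if (object$intercept) cbind(`(Intercept)` = rep(1, nrow(X)), Z)
        else as.matrix(Z)
  if (ncol(Zf) != object$q)
    stop("Z implies q = ", ncol(Zf), "; model has q = ", object$q,
         call. = FALSE)
  cluster <- as.character(cluster)
  known <- cluster %in% object$clusters
  if (any(!known))
    message(sum(!known), " observation(s) in unseen clusters: ",
            "fixed-effect prediction only")
  re <- numeric(nrow(X))
  if (any(known)) {
    bk <- object$b[cluster[known], , drop = FALSE]
    re[known] <- rowSums(Zf[known, , drop = FALSE] * bk)
  }
  fixed + re
}

#' @export
fitted.merf <- function(object, ...) {
  predict_fixed_learner(object$forest, object$X_train)
}

#' @export
residuals.merf <- function(object, ...) {
  stop("residuals require the training response; use y - predict(fit, X, Z, ",
       "cluster, type = 'full') on the training data", call. = FALSE)
}

#' @export
print.merf <- function(x, ...) {
  cat("Mixed-effect random forest\n")
  cat("  observations:", x$n, " clusters:", length(x$clusters),
      " q:", x$q, "\n")
  cat("  fixed effect:", x$forest$type,
      if (x$forest$type == "ranger")
        paste0("(", x$hp$n_estimators, " trees)") else "", "\n")
  cat("  sigma2:", signif(x$sigma2, 4),
      " iterations:", length(x$gll_trace),
      " converged:", x$converged, "\n")
  invisible(x)
}

#' @export
summary.merf <- function(object, ...) {
  out <- list(n = object$n, m = length(object$clusters), q = object$q,
              sigma2 = object$sigma2, D_diag = diag(object$D),
              gll_trace = object$gll_trace, converged = object$converged,
              hp = object$hp)
  class(out) <- "summary.merf"
  out
}

#' @export
print.summary.merf <- function(x, ...) {
  cat("Mixed-effect random forest fit\n")
  cat("  n =", x$n, ", clusters =", x$m, ", q =", x$q, "\n")
  cat("  residual variance sigma2 =", signif(x$sigma2, 5), "\n")
  cat("  diag(D):\n")
  print(signif(x$D_diag, 4))
  cat("  GLL trace:", paste(signif(x$gll_trace, 6), collapse = " -> "), "\n")
  cat("  converged:", x$converged, "\n")
  invisible(x)
}

#' Extract the per-cluster random-effect coefficients (BLUPs)
#' @param object a fitted [merf()]
#' @param ... unused
#' @return matrix clusters x q
#' @export
coef.merf <- function(object, ...) object$b

#' @export
plot.merf <- function(x, ...) {
  graphics::plot(seq_along(x$gll_trace), x$gll_trace, type = "b",
                 xlab = "EM iteration", ylab = "GLL",
                 main = "Generalized log-likelihood trace", ...)
  invisible(x)
}

#' Per-cluster gene-effect estimates (total random effect)
#'
#' Evaluates each training cluster's random-effect prediction `z' b_i` at
#' its (cluster-constant) gene feature vector: the model's estimate of the
#' gene-level depletion effect.  When gene features are identical within a
#' cluster only this total — not the individual coefficients — is
#' identified.
#'
#' @param object a fitted [merf()]
#' @param Z the training random-effect design (n x k, as passed to [merf()])
#' @param cluster the training cluster labels
#' @return named numeric vector, one value per cluster
#' @export
cluster_effects <- function(object, Z = NULL, cluster) {
  stopifnot(inherits(object, "merf"))
  cluster <- as.character(cluster)
  Zf <- if (object$intercept) cbind(`(Intercept)` = rep(1, length(cluster)), Z)
        else as.matrix(Z)
  zb <- rowSums(Zf * object$b[cluster, , drop = FALSE])
  out <- tapply(zb, cluster, mean)
  out[object$clusters]
}

#' Seeded random search over the forest hyperparameter space
#'
#' Draws `budget` configurations uniformly from the supported space
#' (bootstrap in \{TRUE, FALSE\}; trees 50..1000 by 10; feature fraction in
#' (0, 1\]; depth 2..30; leaf 1..20; split 2..20), evaluates `objective`
#' (larger is better; a natural choice is the median per-gene Spearman
#' correlation under gene-wise cross-validation) and returns the best
#' configuration.  Failing evaluations score `-Inf` and are kept in the
#' trials log.
#'
#' @param objective function(hp) -> numeric score
#' @param budget number of configurations to try (>= 1)
#' @param seed RNG seed for the search
#' @return the best `merf_hyperparams`, with a `trials` attribute
#'   (data.frame of configurations and scores)
#' @export
tune_hyperparameters <- function(objective, budget = 20L, seed = 1L) {
  stopifnot(budget >= 1L)
  rng <- local_rng(seed)
  trials <- vector("list", budget)
  scores <- numeric(budget)
  for (t in seq_len(budget)) {
    hp <- merf_hyperparams(
      bootstrap = sample(c(TRUE, FALSE), 1L),
      n_estimators = sample(seq(50L, 1000L, by = 10L), 1L),
      max_features = stats::runif(1L, .Machine$double.eps, 1),
      max_depth = sample(2:30, 1L),
      min_samples_leaf = sample(1:20, 1L),
      min_samples_split = sample(2:20, 1L))
    trials[[t]] <- hp
    scores[t] <- tryCatch(as.numeric(objective(hp)), error = function(e) {
      message("trial ", t, " failed: ", conditionMessage(e))
      -Inf
    })
  }
  rng()  # restore RNG state
  best <- trials[[which.max(scores)]]
  attr(best, "trials") <- data.frame(
    trial = seq_len(budget),
    bootstrap = vapply(trials, `[[`, logical(1), "bootstrap"),
    n_estimators = vapply(trials, `[[`, integer(1), "n_estimators"),
    max_features = vapply(trials, `[[`, numeric(1), "max_features"),
    max_depth = vapply(trials, `[[`, integer(1), "max_depth"),
    min_samples_leaf = vapply(trials, `[[`, integer(1), "min_samples_leaf"),
    min_samples_split = vapply(trials, `[[`, integer(1), "min_samples_split"),
    score = scores)
  best
}

# Seed the RNG locally; returns a function restoring the previous state.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
    invisible(NULL)
  }
}
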