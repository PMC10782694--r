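# Feature attribution for the fixed-effect forest.
#
# The exact backend is a from-scratch implementation of the path-dependent
# TreeSHAP recursion over the extracted ranger trees, with node covers taken
# from routing the training data.  A model-agnostic permutation backend is
# also provided; both satisfy local accuracy (attributions + base value =
# prediction) up to floating-point error.

# ---- forest extraction -----------------------------------------------------

# Extract all trees of a ranger forest into flat arrays, with per-node covers
# computed by routing `X_cover` through each tree.
extract_forest <- function(rf, X_cover) {
  stopifnot(inherits(rf, "ranger"))
  feat_names <- colnames(X_cover)
  trees <- lapply(seq_len(rf$num.trees), function(t) {
    ti <- ranger::treeInfo(rf, t)
    o <- order(ti$nodeID)
    ti <- ti[o, , drop = FALSE]
    left <- ti$leftChild + 1L   # node ids 1-based, NA at leaves
    right <- ti$rightChild + 1L
    feat <- match(ti$splitvarName, feat_names)
    tree <- list(left = left, right = right, feat = feat,
                 thr = ti$splitval, terminal = ti$terminal,
                 value = ti$prediction)
    tree$cover <- route_covers(tree, X_cover)
    if (any(tree$cover == 0))
      stop("tree node with zero cover; supply cover data reaching all nodes",
           call. = FALSE)
    tree
  })
  structure(list(trees = trees, feature_names = feat_names),
            class = "extracted_forest")
}

# number of cover rows passing through every node (root gets all)
route_covers <- function(tree, X) {
  nnodes <- length(tree$left)
  counts <- tabulate(rep(1L, nrow(X)), nnodes)
  cur <- rep(1L, nrow(X))
  repeat {
    live <- which(!tree$terminal[cur])
    if (!length(live)) break
    j <- cur[live]
    go_left <- X[cbind(live, tree$feat[j])] <= tree$thr[j]
    nxt <- ifelse(go_left, tree$left[j], tree$right[j])
    cur[live] <- nxt
    counts <- counts + tabulate(nxt, nnodes)
  }
  counts
}

# predict one extracted tree for rows of X (used for verification and by the
# permutation backend on extracted forests)
predict_tree <- function(tree, X) {
  n <- nrow(X)
  cur <- rep(1L, n)
  repeat {
    live <- !tree$terminal[cur]
    if (!any(live)) break
    idx <- which(live)
    j <- cur[idx]
    go_left <- X[cbind(idx, tree$feat[j])] <= tree$thr[j]
    cur[idx] <- ifelse(go_left, tree$left[j], tree$right[j])
  }
  tree$value[cur]
}

predict_extracted <- function(forest, X) {
  preds <- vapply(forest$trees, function(tr) predict_tree(tr, X),
                  numeric(nrow(X)))
  if (is.null(dim(preds))) mean(preds) else rowMeans(preds)
}

# ---- path-dependent TreeSHAP ----------------------------------------------

# Feature path bookkeeping: parallel vectors d (feature), z (cover fraction),
# o (one fraction), w (permutation weights).
path_extend <- function(pth, pz, po, pi) {
  l <- length(pth$w)
  pth$d <- c(pth$d, pi)
  pth$z <- c(pth$z, pz)
  pth$o <- c(pth$o, po)
  pth$w <- c(pth$w, if (l == 0L) 1 else 0)
  if (l > 0L) for (i in l:1L) {
    pth$w[i + 1L] <- pth$w[i + 1L] + po * pth$w[i] * i / (l + 1)
    pth$w[i] <- pz * pth$w[i] * (l + 1 - i) / (l + 1)
  }
  pth
}

path_unwind <- function(pth, i) {
  l <- length(pth$w)
  nn <- pth$w[l]
  oi <- pth$o[i]; zi <- pth$z[i]
  if (l >= 2L) for (j in (l - 1L):1L) {
    if (oi != 0) {
      tmp <- pth$w[j]
      pth$w[j] <- nn * l / (j * oi)
      nn <- tmp - pth$w[j] * zi * (l - j) / l
    } else {
      pth$w[j] <- pth$w[j] * l / (zi * (l - j))
    }
  }
  pth$d <- pth$d[-i]; pth$z <- pth$z[-i]; pth$o <- pth$o[-i]
  pth$w <- pth$w[-l]
  pth
}

path_unwound_sum <- function(pth, i) {
  l <- length(pth$w)
  oi <- pth$o[i]; zi <- pth$z[i]
  total <- 0
  nn <- pth$w[l]
  for (j in (l - 1L):1L) {
    if (oi != 0) {
      tmp <- nn * l / (j * oi)
      total <- total + tmp
      nn <- pth$w[j] - tmp * zi * (l - j) / l
    } else {
      total <- total + pth$w[j] * l / (zi * (l - j))
    }
  }
  total
}

treeshap_one <- function(tree, x, p) {
  phi <- numeric(p)
  recurse <- function(j, pth, pz, po, pi) {
    pth <- path_extend(pth, pz, po, pi)
    if (tree$terminal[j]) {
      l <- length(pth$w)
      if (l >= 2L) for (i in 2L:l) {
        w <- path_unwound_sum(pth, i)
        phi[pth$d[i]] <<- phi[pth$d[i]] +
          w * (pth$o[i] - pth$z[i]) * tree$value[j]
      }
    } else {
      f <- tree$feat[j]
      hot <- if (x[f] <= tree$thr[j]) tree$left[j] else tree$right[j]
      cold <- if (hot == tree$left[j]) tree$right[j] else tree$left[j]
      iz <- 1; io <- 1
      k <- match(f, pth$d)
      if (!is.na(k) && k >= 2L) {
        iz <- pth$z[k]; io <- pth$o[k]
        pth <- path_unwind(pth, k)
      }
      rj <- tree$cover[j]
      recurse(hot, pth, iz * tree$cover[hot] / rj, io, f)
      recurse(cold, pth, iz * tree$cover[cold] / rj, 0, f)
    }
  }
  recurse(1L, list(d = integer(0), z = numeric(0), o = numeric(0),
                   w = numeric(0)), 1, 1, 0L)
  phi
}

tree_base_value <- function(tree) {
  leaves <- which(tree$terminal)
  sum(tree$cover[leaves] / tree$cover[1L] * tree$value[leaves])
}

# ---- public attribution API ------------------------------------------------

#' Per-sample, per-feature attributions for the fixed-effect forest
#'
#' Computes additive feature attributions (SHAP values) for forest
#' predictions.  `method = "exact_tree"` runs the path-dependent TreeSHAP
#' recursion over the extracted trees (deterministic; covers from the
#' training data).  `method = "permutation"` is model-agnostic: attributions
#' are averaged marginal contributions over seeded feature-permutation
#' orders against a background sample.  Both satisfy local accuracy:
#' `base_value + rowSums(values)` equals the model prediction.
#'
#' @param fit a fitted [merf()] (its fixed-effect forest is explained)
#' @param X rows to explain (columns in training order)
#' @param method `"exact_tree"` or `"permutation"`
#' @param background background rows for the permutation method (default: up
#'   to 100 training rows)
#' @param nperm permutation orders per row (permutation method)
#' @param seed RNG seed (permutation method)
#' @return list of class `attribution`: `values` (n x p), `base_value`,
#'   `feature_names`, `prediction`
#' @export
attribute <- function(fit, X, method = c("exact_tree", "permutation"),
                      background = NULL, nperm = 20L, seed = 1L) {
  method <- match.arg(method)
  if (inherits(fit, "merf")) {
    learner <- fit$forest
    if (is.null(background)) {
      bg_n <- min(100L, nrow(fit$X_train))
      background <- fit$X_train[seq_len(bg_n), , drop = FALSE]
    }
    cover <- fit$X_train
  } else stop("fit must be a fitted merf model", call. = FALSE)
  X <- as.matrix(X)
  p <- ncol(X)
  if (!is.null(fit$feature_names) && p != length(fit$feature_names))
    stop("X does not match the model's feature registry", call. = FALSE)

  if (learner$type == "mean") {
    values <- matrix(0, nrow(X), p,
                     dimnames = list(NULL, colnames(X)))
    return(structure(list(values = values, base_value = learner$value,
                          feature_names = colnames(X),
                          prediction = rep(learner$value, nrow(X))),
                     class = "attribution"))
  }

  if (method == "exact_tree") {
    forest <- extract_forest(learner$rf, cover)
    base <- mean(vapply(forest$trees, tree_base_value, numeric(1)))
    vals <- matrix(0, nrow(X), p)
    for (tr in forest$trees) {
      for (i in seq_len(nrow(X))) {
        vals[i, ] <- vals[i, ] + treeshap_one(tr, X[i, ], p)
      }
    }
    vals <- vals / length(forest$trees)
    pred <- predict_fixed_learner(learner, X)
  } else {
    restore <- local_rng(seed)
    on.exit(restore())
    bg <- as.matrix(background)
    base <- mean(predict_fixed_learner(learner, bg))
    vals <- matrix(0, nrow(X), p)
    nbg <- nrow(bg)
    for (i in seq_len(nrow(X))) {
      x <- X[i, ]
      acc <- numeric(p)
      for (r in seq_len(nperm)) {
        ord <- sample.int(p)
        # rows 0..p: background rows with the first k features (in ord)
        # replaced by x
        stack <- matrix(0, nbg * (p + 1L), p)
        cur <- bg
        stack[seq_len(nbg), ] <- cur
        for (k in seq_len(p)) {
          cur[, ord[k]] <- x[ord[k]]
          stack[k * nbg + seq_len(nbg), ] <- cur
        }
        colnames(stack) <- colnames(bg)
        pr <- predict_fixed_learner(learner, stack)
        vk <- vapply(0:p, function(k) mean(pr[k * nbg + seq_len(nbg)]),
                     numeric(1))
        acc[ord] <- acc[ord] + diff(vk)
      }
      vals[i, ] <- acc / nperm
    }
    pred <- predict_fixed_learner(learner, X)
  }
  colnames(vals) <- colnames(X)
  structure(list(values = vals, base_value = base,
                 feature_names = colnames(X), prediction = pred),
            class = "attribution")
}

#' @export
print.attribution <- function(x, ...) {
  cat("<attribution> ", nrow(x$values), " samples x ", ncol(x$values),
      " features, base value ", signif(x$base_value, 4), "\n", sep = "")
  err <- max(abs(x$base_value + rowSums(x$values) - x$prediction))
  cat("  max local-accuracy error: ", format(err, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Global feature importance: mean absolute attribution per feature
#' @param attr an [attribute()] result
#' @return data.frame (feature, importance), sorted descending
#' @export
mean_abs_importance <- function(attr) {
  stopifnot(inherits(attr, "attribution"), nrow(attr$values) > 0L)
  imp <- colMeans(abs(attr$values))
  out <- data.frame(feature = names(imp), importance = unname(imp),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$importance), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Observed vs expected attribution for a pair of binary features
#'
#' Stratifies samples into the four presence combinations of two features
#' (-/-, +/-, -/+, +/+) and compares the observed median summed attribution
#' in each stratum with the expectation under additivity: e.g.
#' `expected(+/+) = median(attr_F1 | +/-) + median(attr_F2 | -/+)`.
#' A nonzero deviation flags an interaction between the features.
#'
#' @param attr_F1,attr_F2 per-sample attributions of the two features
#' @param present_F1,present_F2 logical presence indicators (for one-hot
#'   features: indicator equals 1)
#' @return data.frame with one row per combination: `n`, `observed`,
#'   `expected`, `deviation`, `missing`
#' @export
interaction_combination_table <- function(attr_F1, attr_F2,
                                          present_F1, present_F2) {
  stopifnot(length(attr_F1) == length(attr_F2),
            length(present_F1) == length(attr_F1),
            length(present_F2) == length(attr_F1))
  p1 <- as.logical(present_F1); p2 <- as.logical(present_F2)
  strata <- list(`-/-` = !p1 & !p2, `+/-` = p1 & !p2,
                 `-/+` = !p1 & p2, `+/+` = p1 & p2)
  med <- function(v, sel) if (any(sel)) stats::median(v[sel]) else NA_real_
  observed <- vapply(strata, function(s) med(attr_F1 + attr_F2, s), numeric(1))
  expected <- c(
    `-/-` = med(attr_F1, strata$`-/+`) + med(attr_F2, strata$`+/-`),
    `+/-` = NA_real_,
    `-/+` = NA_real_,
    `+/+` = med(attr_F1, strata$`+/-`) + med(attr_F2, strata$`-/+`))
  data.frame(combination = names(strata),
             n = vapply(strata, sum, integer(1)),
             observed = unname(observed),
             expected = unname(expected),
             deviation = unname(observed - expected),
             missing = vapply(strata, function(s) !any(s), logical(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Rank feature pairs by their interaction deviation
#'
#' Screens pairs of binary (one-hot) features by the absolute +/+ deviation
#' of [interaction_combination_table()], a median-based measure of
#' non-additivity of their attributions.
#'
#' @param attr an [attribute()] result
#' @param present n x p logical/0-1 matrix of feature presence (defaults to
#'   the explained matrix itself when it is binary)
#' @param features columns to consider (default: all binary columns)
#' @param top_n number of top pairs to return
#' @param min_n minimum samples required in every stratum
#' @return data.frame of pairs sorted by absolute deviation
#' @export
rank_interaction_pairs <- function(attr, present, features = NULL,
                                   top_n = 100L, min_n = 5L) {
  stopifnot(inherits(attr, "attribution"))
  present <- as.matrix(present) > 0
  if (is.null(features)) features <- colnames(attr$values)
  features <- intersect(features, colnames(present))
  res <- list()
  for (a in seq_along(features)) {
    for (b in seq_len(a - 1L)) {
      f1 <- features[a]; f2 <- features[b]
      tab <- interaction_combination_table(
        attr$values[, f1], attr$values[, f2], present[, f1], present[, f2])
      if (any(tab$n < min_n)) next
      res[[length(res) + 1L]] <- data.frame(
        feature_1 = f1, feature_2 = f2,
        deviation_pp = tab$deviation[tab$combination == "+/+"],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(res)) return(data.frame(feature_1 = character(),
                                      feature_2 = character(),
                                      deviation_pp = numeric()))
  out <- do.call(rbind, res)
  out <- out[order(-abs(out$deviation_pp)), , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, top_n)
}

#' Attribution of the distance feature near vs far from the start codon
#'
#' Summarizes how the model credits the distance-to-start-codon feature for
#' guides inside versus beyond a window (default 60 nt), optionally split by
#' whether the guide targets the first gene of its transcription unit.  More
#' negative attributions indicate the model predicts stronger depletion.
#'
#' @param attr an [attribute()] result containing `feature`
#' @param dist per-sample distances to the start codon (nt)
#' @param first_gene optional logical per-sample first-gene indicator
#' @param window window size in nt
#' @param feature attribution column to profile
#' @return list with `inside_mean`, `outside_mean`, `difference`
#'   (inside - outside) and, when `first_gene` is given, a stratified
#'   data.frame `by_first_gene`
#' @export
distance_effect_profile <- function(attr, dist, first_gene = NULL,
                                    window = 60L,
                                    feature = "dist_start_codon") {
  stopifnot(inherits(attr, "attribution"))
  if (!feature %in% colnames(attr$values))
    stop("feature '", feature, "' not in the attribution matrix",
         call. = FALSE)
  v <- attr$values[, feature]
  stopifnot(length(dist) == length(v))
  inside <- dist < window
  res <- list(
    inside_mean = if (any(inside)) mean(v[inside]) else NA_real_,
    outside_mean = if (any(!inside)) mean(v[!inside]) else NA_real_)
  res$difference <- res$inside_mean - res$outside_mean
  res$missing_stratum <- !any(inside) || !any(!inside)
  if (!is.null(first_gene)) {
    fg <- as.logical(first_gene)
    cells <- expand.grid(inside = c(TRUE, FALSE), first_gene = c(TRUE, FALSE))
    cells$mean_attr <- mapply(function(i, f) {
      s <- inside == i & fg == f
      if (any(s)) mean(v[s]) else NA_real_
    }, cells$inside, cells$first_gene)
    cells$n <- mapply(function(i, f) sum(inside == i & fg == f),
                      cells$inside, cells$first_gene)
    res$by_first_gene <- cells
  }
  res
}
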