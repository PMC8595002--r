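# Base classifiers.  SVM: cubic polynomial kernel, C = 100, dual solved with
# quadprog.  k-NN: k = 1 via FNN.  The four tree learners share the compiled
# entropy-tree core: c45_like (gain ratio, pessimistic pruning), rep_tree
# (information gain, reduced-error pruning on a held-out third), random_tree
# (log2(p)+1 features per node, unpruned), rf (bagged forest of 100 such
# trees with sqrt(p) features per node).

#' Base learner specification
#'
#' Defaults follow the stated settings: SVM with a cubic polynomial kernel
#' and regularization 100; k-NN with k = 1; random forest with 100 trees.
#'
#' @param kind One of `"svm"`, `"knn"`, `"rf"`, `"c45_like"`, `"rep_tree"`,
#'   `"random_tree"`.
#' @param ... Hyperparameter overrides (e.g. `cost`, `k`, `n_trees`,
#'   `min_leaf`, `max_depth`).
#' @return Object of class `base_learner_spec`.
#' @export
base_learner_spec <- function(kind = c("svm", "knn", "rf", "c45_like",
                                       "rep_tree", "random_tree"), ...) {
  kind <- match.arg(kind)
  defaults <- switch(kind,
    svm = list(cost = 100, degree = 3, coef0 = 1),
    knn = list(k = 1L, normalize = TRUE),
    rf = list(n_trees = 100L, min_leaf = 1L, max_depth = -1L),
    c45_like = list(min_leaf = 2L, max_depth = -1L, cf = 0.25),
    rep_tree = list(min_leaf = 2L, max_depth = -1L, holdout_fraction = 1 / 3),
    random_tree = list(min_leaf = 1L, max_depth = -1L))
  hp <- utils::modifyList(defaults, list(...))
  structure(list(kind = kind, hyperparameters = hp),
            class = "base_learner_spec")
}

#' @export
print.base_learner_spec <- function(x, ...) {
  hp <- paste(names(x$hyperparameters),
              vapply(x$hyperparameters, format, ""), sep = "=",
              collapse = ", ")
  cat(sprintf("<base_learner_spec> %s (%s)\n", x$kind, hp))
  invisible(x)
}

as_xy <- function(features) {
  if (inherits(features, "feature_matrix")) {
    list(x = features$x, y = features$labels)
  } else if (is.list(features) && !is.null(features$x)) {
    list(x = as.matrix(features$x), y = as.integer(features$labels))
  } else {
    stop("features must be a feature_matrix or a list(x, labels)")
  }
}

#' Train a base classifier
#'
#' @param spec A [base_learner_spec()].
#' @param features A [feature_matrix()] (or `list(x, labels)`).
#' @param seed Integer seed; training is deterministic given it.
#' @return Object of class `base_model`, usable with [predict_base()].
#' @export
train_base <- function(spec, features, seed = 1L) {
  stopifnot(inherits(spec, "base_learner_spec"))
  d <- as_xy(features)
  if (length(unique(d$y)) < 2L) {
    stop("training data contains a single class; cannot fit a classifier")
  }
  if (anyNA(d$x)) stop("training data contains missing values")
  fit <- withr::with_seed(as.integer(seed), switch(spec$kind,
    svm = train_svm(d$x, d$y, spec$hyperparameters),
    knn = train_knn(d$x, d$y, spec$hyperparameters),
    rf = train_rf(d$x, d$y, spec$hyperparameters),
    c45_like = train_c45(d$x, d$y, spec$hyperparameters),
    rep_tree = train_rep(d$x, d$y, spec$hyperparameters),
    random_tree = train_random_tree(d$x, d$y, spec$hyperparameters)))
  structure(list(kind = spec$kind, fit = fit, spec = spec,
                 classes = c(1L, 2L), p = ncol(d$x)),
            class = "base_model")
}

#' Predict with a base classifier
#'
#' @param model A [train_base()] model.
#' @param x Numeric matrix with the training feature width.
#' @return List with `labels` (integer) and `scores` (n x 2 matrix of class
#'   probabilities summing to 1 per row; column order `1`, `2`).
#' @export
predict_base <- function(model, x) {
  stopifnot(inherits(model, "base_model"))
  x <- as.matrix(x)
  if (ncol(x) != model$p) {
    stop("feature width ", ncol(x), " does not match training width ", model$p)
  }
  out <- switch(model$kind,
    svm = predict_svm(model$fit, x),
    knn = predict_knn(model$fit, x),
    rf = predict_rf(model$fit, x),
    c45_like = ,
    rep_tree = ,
    random_tree = predict_tree_model(model$fit, x))
  colnames(out$scores) <- c("1", "2")
  out
}

# ---- SVM --------------------------------------------------------------------
# Kernel K(u, v) = (1 + u.v / p)^degree on standardized columns; soft-margin
# dual solved with quadprog (ridge-stabilized).  Probability scores come from
# a logistic link fitted on the training decision values; labels from the
# sign of the decision value.

poly_kernel <- function(A, B, degree, coef0) {
  (coef0 + tcrossprod(A, B) / ncol(A))^degree
}

train_svm <- function(x, y, hp) {
  ctr <- colMeans(x)
  scl <- apply(x, 2L, stats::sd)
  scl[scl < 1e-12] <- 1
  xs <- scale(x, center = ctr, scale = scl)
  ys <- ifelse(y == 1L, 1, -1)
  n <- nrow(xs)
  K <- poly_kernel(xs, xs, hp$degree, hp$coef0)
  D <- (ys %o% ys) * K
  ridge <- 1e-8 * mean(diag(D))
  sol <- NULL
  for (tries in 1:6) {
    sol <- tryCatch(
      quadprog::solve.QP(
        Dmat = D + diag(ridge, n), dvec = rep(1, n),
        Amat = cbind(ys, diag(n), -diag(n)),
        bvec = c(0, rep(0, n), rep(-hp$cost, n)), meq = 1L),
      error = function(e) NULL)
    if (!is.null(sol)) break
    ridge <- ridge * 100
  }
  if (is.null(sol)) stop("SVM dual QP failed to solve")
  alpha <- pmin(pmax(sol$solution, 0), hp$cost)
  sv <- alpha > 1e-8 * hp$cost
  margin <- sv & alpha < hp$cost * (1 - 1e-8)
  if (!any(margin)) margin <- sv
  f_no_b <- as.vector(K %*% (alpha * ys))
  b <- mean(ys[margin] - f_no_b[margin])
  dec <- f_no_b + b
  # logistic link for ranking scores (guard perfect separation)
  lf <- suppressWarnings(stats::glm((y == 1L) ~ dec, family = stats::binomial()))
  list(xs = xs[sv, , drop = FALSE], coef = (alpha * ys)[sv], b = b,
       ctr = ctr, scl = scl, degree = hp$degree, coef0 = hp$coef0,
       link = stats::coef(lf))
}

predict_svm <- function(fit, x) {
  xs <- scale(x, center = fit$ctr, scale = fit$scl)
  dec <- as.vector(poly_kernel(xs, fit$xs, fit$degree, fit$coef0) %*% fit$coef) +
    fit$b
  labels <- ifelse(dec >= 0, 1L, 2L)
  eta <- fit$link[1] + fit$link[2] * dec
  p1 <- stats::plogis(pmin(pmax(eta, -35), 35))
  list(labels = labels, scores = cbind(p1, 1 - p1))
}

# ---- k-NN -------------------------------------------------------------------
# Euclidean distance on per-attribute range-normalized features (the common
# toolkit default for instance-based learners); constant attributes are left
# unscaled.  `normalize = FALSE` gives the raw-distance, rotation-equivariant
# variant.

train_knn <- function(x, y, hp) {
  if (isTRUE(hp$normalize)) {
    lo <- apply(x, 2L, min)
    rng <- apply(x, 2L, max) - lo
    rng[rng < 1e-12] <- 1
  } else {
    lo <- rep(0, ncol(x))
    rng <- rep(1, ncol(x))
  }
  list(x = sweep(sweep(x, 2L, lo), 2L, rng, `/`), y = y, k = hp$k,
       lo = lo, rng = rng)
}

predict_knn <- function(fit, x) {
  k <- fit$k
  xs <- sweep(sweep(x, 2L, fit$lo), 2L, fit$rng, `/`)
  nb <- FNN::get.knnx(fit$x, xs, k = k)$nn.index
  votes1 <- matrix(fit$y[nb] == 1L, nrow = nrow(x))
  n1 <- rowSums(votes1)
  labels <- ifelse(n1 * 2L >= k + 1L, 1L, ifelse(n1 * 2L == k, 1L, 2L))
  # ties (k even, n1 == k/2) resolved to the lowest class label
  p1 <- (n1 + 0.5) / (k + 1)  # Laplace-ish smoothing for a usable AUC score
  list(labels = labels, scores = cbind(p1, 1 - p1))
}

# ---- trees ------------------------------------------------------------------

grow_tree <- function(x, y, mtry, min_leaf, max_depth, criterion) {
  cpp_grow_tree(x, as.integer(y == 2L), as.integer(mtry), 2L,
                as.integer(min_leaf), as.integer(max_depth), criterion,
                sample.int(.Machine$integer.max, 1L))
}

tree_scores <- function(tree, x) {
  leaf <- cpp_tree_apply(tree$feature, tree$threshold, tree$left, tree$right,
                         as.matrix(x))
  n0 <- tree$n0[leaf]
  n1 <- tree$n1[leaf]
  cbind((n0 + 1) / (n0 + n1 + 2), (n1 + 1) / (n0 + n1 + 2))
}

tree_n_nodes <- function(tree) {
  # reachable nodes only (pruning marks subtree roots as leaves)
  seen <- logical(length(tree$feature))
  stack <- 1L
  while (length(stack) > 0L) {
    nd <- stack[[1L]]
    stack <- stack[-1L]
    seen[nd] <- TRUE
    if (tree$feature[nd] >= 0L) {
      stack <- c(stack, tree$left[nd] + 1L, tree$right[nd] + 1L)
    }
  }
  sum(seen)
}

train_random_tree <- function(x, y, hp) {
  mtry <- ceiling(log2(ncol(x)) + 1)
  list(trees = list(grow_tree(x, y, mtry, hp$min_leaf, hp$max_depth, "gain")))
}

train_rf <- function(x, y, hp) {
  n <- nrow(x)
  mtry <- max(1L, floor(sqrt(ncol(x))))
  trees <- vector("list", hp$n_trees)
  for (b in seq_len(hp$n_trees)) {
    idx <- sample.int(n, n, replace = TRUE)
    trees[[b]] <- grow_tree(x[idx, , drop = FALSE], y[idx], mtry,
                            hp$min_leaf, hp$max_depth, "gain")
  }
  list(trees = trees)
}

# C4.5-flavoured pessimistic error pruning (CF = 0.25 upper confidence bound
# on the leaf error rate), bottom-up collapse when the leaf estimate does not
# exceed the subtree estimate.
ucf_errors <- function(e, n, z) {
  if (n == 0) return(0)
  f <- e / n
  n * (f + z^2 / (2 * n) + z * sqrt(f * (1 - f) / n + z^2 / (4 * n^2))) /
    (1 + z^2 / n)
}

prune_pessimistic <- function(tree, cf) {
  z <- stats::qnorm(1 - cf)
  est <- function(nd) {
    n <- tree$n0[nd] + tree$n1[nd]
    e_leaf <- min(tree$n0[nd], tree$n1[nd])
    leaf_est <- ucf_errors(e_leaf, n, z)
    if (tree$feature[nd] < 0L) return(leaf_est)
    sub_est <- est(tree$left[nd] + 1L) + est(tree$right[nd] + 1L)
    if (leaf_est <= sub_est + 0.1) {
      tree$feature[nd] <<- -1L
      leaf_est
    } else {
      sub_est
    }
  }
  est(1L)
  tree
}

train_c45 <- function(x, y, hp) {
  tree <- grow_tree(x, y, ncol(x), hp$min_leaf, hp$max_depth, "gainratio")
  pre <- tree_n_nodes(tree)
  tree <- prune_pessimistic(tree, hp$cf)
  list(trees = list(tree), n_nodes_pre = pre, n_nodes_post = tree_n_nodes(tree))
}

# reduced-error pruning: grow on two thirds, collapse any node whose
# majority-label error on the held-out third does not exceed its subtree's.
prune_reduced_error <- function(tree, xh, yh) {
  route <- function(nd, idx) {
    errs_leaf <- sum(yh[idx] != (if (tree$n1[nd] > tree$n0[nd]) 2L else 1L))
    if (tree$feature[nd] < 0L) return(errs_leaf)
    go_left <- xh[idx, tree$feature[nd] + 1L] <= tree$threshold[nd]
    errs_sub <- route(tree$left[nd] + 1L, idx[go_left]) +
      route(tree$right[nd] + 1L, idx[!go_left])
    if (errs_leaf <= errs_sub) {
      tree$feature[nd] <<- -1L
      errs_leaf
    } else {
      errs_sub
    }
  }
  route(1L, seq_len(nrow(xh)))
  tree
}

train_rep <- function(x, y, hp) {
  n <- nrow(x)
  n_hold <- max(1L, floor(n * hp$holdout_fraction))
  hold <- sample.int(n, n_hold)
  grow <- setdiff(seq_len(n), hold)
  if (length(unique(y[grow])) < 2L) {   # degenerate split: grow on everything
    grow <- seq_len(n)
  }
  tree <- grow_tree(x[grow, , drop = FALSE], y[grow], ncol(x), hp$min_leaf,
                    hp$max_depth, "gain")
  pre <- tree_n_nodes(tree)
  tree <- prune_reduced_error(tree, x[hold, , drop = FALSE], y[hold])
  list(trees = list(tree), n_nodes_pre = pre, n_nodes_post = tree_n_nodes(tree))
}

predict_tree_model <- function(fit, x) {
  scores <- tree_scores(fit$trees[[1L]], x)
  if (length(fit$trees) > 1L) {
    for (b in 2L:length(fit$trees)) {
      scores <- scores + tree_scores(fit$trees[[b]], x)
    }
    scores <- scores / length(fit$trees)
  }
  labels <- ifelse(scores[, 2L] > scores[, 1L], 2L, 1L)
  list(labels = labels, scores = scores)
}

predict_rf <- predict_tree_model
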