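# Rotation Forest and Random Subspace meta-learners over any base classifier.
#
# Rotation Forest member: random partition of the feature indices into
# subgroups of group_size; per subgroup a random class subset is drawn and a
# 75% instance subsample taken, PCA is fitted on those columns keeping ALL
# components, and the loadings form one orthonormal block of the member's
# p x p rotation matrix; the base learner trains on the rotated features and
# prediction averages member class-scores.
#
# Random Subspace member: a uniformly drawn duplicate-free feature subset of
# size B = floor(fraction * p), all training instances; prediction is a simple
# majority vote with ties broken toward the lowest class label.

#' Rotation Forest configuration
#'
#' @param n_members Committee size (the ensemble size is not dictated by the
#'   method; 10 is the package default and is reported with results).
#' @param group_size Features per PCA subgroup; the number of subgroups is
#'   `Q = ceiling(n_features / group_size)`.
#' @param class_subset_fraction Probability with which each class enters a
#'   subgroup's PCA sample (at least one class is always kept).
#' @param bootstrap_fraction Fraction of the selected instances subsampled
#'   (without replacement) before fitting each subgroup PCA.
#' @param seed Integer seed.
#' @return Object of class `rotation_forest_config`.
#' @export
rotation_forest_config <- function(n_members = 10L, group_size = 3L,
                                   class_subset_fraction = 0.75,
                                   bootstrap_fraction = 0.75, seed = 1L) {
  if (n_members < 1 || n_members != round(n_members)) {
    stop("n_members must be a positive integer")
  }
  if (group_size < 1 || group_size != round(group_size)) {
    stop("group_size must be a positive integer")
  }
  if (class_subset_fraction <= 0 || class_subset_fraction > 1) {
    stop("class_subset_fraction must lie in (0, 1]")
  }
  if (bootstrap_fraction <= 0 || bootstrap_fraction > 1) {
    stop("bootstrap_fraction must lie in (0, 1]")
  }
  structure(list(n_members = as.integer(n_members),
                 group_size = as.integer(group_size),
                 class_subset_fraction = class_subset_fraction,
                 bootstrap_fraction = bootstrap_fraction,
                 seed = as.integer(seed)),
            class = "rotation_forest_config")
}

#' Random Subspace configuration
#'
#' @param n_members Committee size.
#' @param subspace_fraction Fraction of features per member,
#'   `B = floor(fraction * n_features)` (must give B >= 1).
#' @param seed Integer seed.
#' @return Object of class `random_subspace_config`.
#' @export
random_subspace_config <- function(n_members = 10L, subspace_fraction = 0.5,
                                   seed = 1L) {
  if (n_members < 1 || n_members != round(n_members)) {
    stop("n_members must be a positive integer")
  }
  if (subspace_fraction <= 0 || subspace_fraction > 1) {
    stop("subspace_fraction must lie in (0, 1]")
  }
  structure(list(n_members = as.integer(n_members),
                 subspace_fraction = subspace_fraction,
                 seed = as.integer(seed)),
            class = "random_subspace_config")
}

rotation_matrix_for_member <- function(x, y, config) {
  p <- ncol(x)
  groups <- split(sample.int(p),
                  rep(seq_len(ceiling(p / config$group_size)),
                      each = config$group_size, length.out = p))
  R <- matrix(0, p, p)
  for (g in groups) {
    g <- sort(g)
    classes <- c(1L, 2L)
    keep_cls <- classes[stats::runif(2) < config$class_subset_fraction]
    if (length(keep_cls) == 0L) keep_cls <- sample(classes, 1L)
    rows <- which(y %in% keep_cls)
    take <- max(2L, floor(length(rows) * config$bootstrap_fraction))
    rows <- rows[sample.int(length(rows), min(take, length(rows)))]
    block <- if (length(rows) < 2L) {
      diag(length(g))
    } else {
      pca_decompose(x[rows, g, drop = FALSE], center = TRUE)$loadings
    }
    R[g, g] <- block
  }
  R
}

#' Train a Rotation Forest ensemble
#'
#' @param config A [rotation_forest_config()].
#' @param base A [base_learner_spec()].
#' @param features A [feature_matrix()] (or `list(x, labels)`).
#' @return Object of class `ensemble_model`.
#' @export
train_rotation_forest <- function(config, base, features) {
  stopifnot(inherits(config, "rotation_forest_config"),
            inherits(base, "base_learner_spec"))
  d <- as_xy(features)
  if (config$group_size > ncol(d$x)) {
    stop("group_size (", config$group_size, ") exceeds the feature count (",
         ncol(d$x), ")")
  }
  members <- withr::with_seed(config$seed, {
    lapply(seq_len(config$n_members), function(m) {
      R <- rotation_matrix_for_member(d$x, d$y, config)
      seed_m <- sample.int(.Machine$integer.max, 1L)
      fit <- train_base(base, list(x = d$x %*% R, labels = d$y), seed = seed_m)
      list(rotation = R, fit = fit)
    })
  })
  structure(list(method = "rotation_forest", members = members,
                 base_spec = base, config = config, classes = c(1L, 2L),
                 p = ncol(d$x)),
            class = "ensemble_model")
}

#' Train a Random Subspace ensemble
#'
#' @param config A [random_subspace_config()].
#' @param base A [base_learner_spec()].
#' @param features A [feature_matrix()] (or `list(x, labels)`).
#' @return Object of class `ensemble_model`.
#' @export
train_random_subspace <- function(config, base, features) {
  stopifnot(inherits(config, "random_subspace_config"),
            inherits(base, "base_learner_spec"))
  d <- as_xy(features)
  p <- ncol(d$x)
  B <- floor(config$subspace_fraction * p)
  if (B < 1L) stop("subspace_fraction yields an empty feature subset (B < 1)")
  members <- withr::with_seed(config$seed, {
    lapply(seq_len(config$n_members), function(m) {
      subset <- sort(sample.int(p, B))
      seed_m <- if (m == 1L && B == p) {
        config$seed  # full-space single member reproduces the bare learner
      } else {
        sample.int(.Machine$integer.max, 1L)
      }
      fit <- train_base(base, list(x = d$x[, subset, drop = FALSE],
                                   labels = d$y), seed = seed_m)
      list(subset = subset, fit = fit)
    })
  })
  structure(list(method = "random_subspace", members = members,
                 base_spec = base, config = config, classes = c(1L, 2L),
                 p = p),
            class = "ensemble_model")
}

#' @export
print.ensemble_model <- function(x, ...) {
  cat(sprintf("<ensemble_model> %s, %d member(s), base = %s, %d features\n",
              x$method, length(x$members), x$base_spec$kind, x$p))
  invisible(x)
}

#' Predict with an ensemble
#'
#' Rotation Forest averages member class-scores and takes the argmax;
#' Random Subspace takes a simple majority vote over member labels (ties to
#' the lowest class label).  Score rows always sum to 1.
#'
#' @param model An `ensemble_model`.
#' @param features A [feature_matrix()], `list(x, labels)` or plain matrix
#'   with the training feature width.
#' @return List with `labels` and `scores` (n x 2).
#' @export
predict_ensemble <- function(model, features) {
  stopifnot(inherits(model, "ensemble_model"))
  x <- if (is.matrix(features)) features else as_xy(features)$x
  if (ncol(x) != model$p) {
    stop("feature width ", ncol(x), " does not match training width ", model$p)
  }
  n <- nrow(x)
  scores <- matrix(0, n, 2L)
  votes1 <- numeric(n)
  for (mem in model$members) {
    px <- if (model$method == "rotation_forest") {
      x %*% mem$rotation
    } else {
      x[, mem$subset, drop = FALSE]
    }
    pr <- predict_base(mem$fit, px)
    scores <- scores + pr$scores
    votes1 <- votes1 + (pr$labels == 1L)
  }
  scores <- scores / length(model$members)
  labels <- if (model$method == "random_subspace") {
    ifelse(votes1 >= length(model$members) - votes1, 1L, 2L)
  } else {
    ifelse(scores[, 1L] >= scores[, 2L], 1L, 2L)
  }
  colnames(scores) <- c("1", "2")
  list(labels = labels, scores = scores)
}

#' @export
predict.ensemble_model <- function(object, newdata, ...) {
  predict_ensemble(object, newdata)
}

#' Save a trained ensemble to a versioned bundle
#'
#' Writes `manifest.json` (format version, method, base learner, committee
#' size) plus the binary model payload.  [load_model()] restores a model whose
#' predictions are bit-identical.
#'
#' @param model An `ensemble_model`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
save_model <- function(model, dir) {
  stopifnot(inherits(model, "ensemble_model"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(format = "mieeg-model", version = 1L,
                   method = model$method, base = model$base_spec$kind,
                   n_members = length(model$members), n_features = model$p)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  saveRDS(model, file.path(dir, "model.rds"), version = 2L)
  invisible(dir)
}

#' Load an ensemble saved by [save_model()]
#' @param dir Bundle directory.
#' @return The `ensemble_model`.
#' @export
load_model <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stop("not a model bundle (missing manifest.json): ", dir)
  manifest <- jsonlite::read_json(mf)
  if (!identical(manifest$format, "mieeg-model")) {
    stop("unrecognized bundle format: ", manifest$format)
  }
  readRDS(file.path(dir, "model.rds"))
}
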