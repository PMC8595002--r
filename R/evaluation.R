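# Confusion-count metrics, ROC AUC, stratified k-fold cross-validation and
# the per-subject / pooled experiment grid.  Class 1 (right hand) is the
# positive class for tp/fp bookkeeping.

#' Confusion counts
#'
#' @param tp,tn,fp,fn Non-negative integers; class 1 is positive.
#' @return Object of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, tn, fp, fn) {
  v <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(v < 0) || any(v != round(v))) {
    stop("confusion counts must be non-negative integers")
  }
  structure(as.list(stats::setNames(as.integer(v), names(v))),
            class = "confusion_counts")
}

counts_from_predictions <- function(truth, predicted) {
  confusion_counts(tp = sum(truth == 1L & predicted == 1L),
                   tn = sum(truth == 2L & predicted == 2L),
                   fp = sum(truth == 2L & predicted == 1L),
                   fn = sum(truth == 1L & predicted == 2L))
}

sum_counts <- function(count_list) {
  confusion_counts(tp = sum(vapply(count_list, `[[`, integer(1), "tp")),
                   tn = sum(vapply(count_list, `[[`, integer(1), "tn")),
                   fp = sum(vapply(count_list, `[[`, integer(1), "fp")),
                   fn = sum(vapply(count_list, `[[`, integer(1), "fn")))
}

#' Classification accuracy in percent
#'
#' `100 * (tp + tn) / (tp + tn + fp + fn)`.
#'
#' @param counts A [confusion_counts()].
#' @return Percent accuracy.
#' @export
accuracy <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  total <- counts$tp + counts$tn + counts$fp + counts$fn
  if (total == 0L) stop("accuracy undefined for zero total count")
  100 * (counts$tp + counts$tn) / total
}

#' F-measure of the positive class
#'
#' `tp / (tp + (fp + fn) / 2)`; returns 0 with a warning in the degenerate
#' case tp = fp = fn = 0 (no positives anywhere).
#'
#' @param counts A [confusion_counts()].
#' @return Value in \[0, 1\].
#' @export
f_measure <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  denom <- counts$tp + (counts$fp + counts$fn) / 2
  if (denom == 0) {
    warning("F-measure degenerate (tp = fp = fn = 0); returning 0")
    return(0)
  }
  counts$tp / denom
}

#' True-positive and false-positive rates
#'
#' `TPR = tp / (tp + fn)`, `FPR = fp / (fp + tn)`.
#'
#' @param counts A [confusion_counts()].
#' @return Named numeric vector `c(tpr, fpr)`.
#' @export
tpr_fpr <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  if (counts$tp + counts$fn == 0L) stop("TPR undefined: no positive instances")
  if (counts$fp + counts$tn == 0L) stop("FPR undefined: no negative instances")
  c(tpr = counts$tp / (counts$tp + counts$fn),
    fpr = counts$fp / (counts$fp + counts$tn))
}

#' Area under the ROC curve
#'
#' Trapezoidal area of the ROC traced over all score thresholds; tied scores
#' cross the threshold simultaneously, which equals the rank-statistic
#' (Mann-Whitney) formulation with half credit for ties.
#'
#' @param scores Positive-class (class 1) scores, one per instance.
#' @param labels True labels in \{1, 2\}.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(scores, labels) {
  if (length(scores) != length(labels)) stop("scores/labels length mismatch")
  pos <- labels == 1L
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L) {
    stop("AUC undefined: both classes must be present")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> tp %d, tn %d, fp %d, fn %d\n",
              x$tp, x$tn, x$fp, x$fn))
  invisible(x)
}

#' Specification of a classifier (ensemble + base) for evaluation
#'
#' @param base A [base_learner_spec()].
#' @param ensemble `"rotation_forest"`, `"random_subspace"`, or `"none"` for
#'   the bare base learner.
#' @param config The matching ensemble configuration (ignored for `"none"`);
#'   defaults are used when `NULL`.
#' @return Object of class `model_spec`.
#' @export
model_spec <- function(base, ensemble = c("rotation_forest", "random_subspace",
                                          "none"), config = NULL) {
  ensemble <- match.arg(ensemble)
  stopifnot(inherits(base, "base_learner_spec"))
  structure(list(base = base, ensemble = ensemble, config = config),
            class = "model_spec")
}

train_model_spec <- function(spec, features, seed) {
  if (spec$ensemble == "none") {
    return(train_base(spec$base, features, seed = seed))
  }
  cfg <- spec$config
  if (spec$ensemble == "rotation_forest") {
    if (is.null(cfg)) cfg <- rotation_forest_config()
    cfg$seed <- as.integer(seed)
    train_rotation_forest(cfg, spec$base, features)
  } else {
    if (is.null(cfg)) cfg <- random_subspace_config()
    cfg$seed <- as.integer(seed)
    train_random_subspace(cfg, spec$base, features)
  }
}

predict_model_spec <- function(model, x) {
  if (inherits(model, "ensemble_model")) predict_ensemble(model, x)
  else predict_base(model, x)
}

spec_id <- function(spec) {
  ens <- switch(spec$ensemble, rotation_forest = "RoF",
                random_subspace = "RSM", none = "bare")
  paste0(ens, "+", spec$base$kind)
}

# Folds are stratified by class; when subject codes are available each
# subject-by-class stratum is additionally spread evenly across folds (class
# totals per fold stay exact), which removes the below-chance bias that
# subject clustering otherwise induces on label-independent data.
stratified_folds <- function(labels, n_folds, subjects = NULL) {
  for (cls in sort(unique(labels))) {
    if (sum(labels == cls) < n_folds) {
      stop("class ", cls, " has ", sum(labels == cls),
           " instances; cannot stratify into ", n_folds, " folds")
    }
  }
  if (is.null(subjects)) subjects <- rep("", length(labels))
  fold <- integer(length(labels))
  for (cls in sort(unique(labels))) {
    offset <- 0L  # rotate start fold so small strata still balance classes
    for (subj in sort(unique(subjects))) {
      idx <- which(labels == cls & subjects == subj)
      if (length(idx) == 0L) next
      f <- ((offset + seq_along(idx) - 1L) %% n_folds) + 1L
      fold[idx[sample.int(length(idx))]] <- f
      offset <- offset + length(idx)
    }
  }
  fold
}

#' Stratified k-fold cross-validation of a classifier
#'
#' Folds are stratified by class and deterministic under the seed.  Accuracy
#' and F-measure are computed from the summed per-fold confusion counts; AUC
#' from the pooled per-instance scores (each instance is scored exactly once,
#' by the fold that held it out).
#'
#' @param features A [feature_matrix()].
#' @param spec A [model_spec()].
#' @param n_folds Number of folds (default 10).
#' @param seed Integer seed governing fold assignment and member training.
#' @return Object of class `eval_report` with `accuracy` (percent),
#'   `f_measure`, `auc`, `per_fold` confusion counts, `scheme`,
#'   `classifier_id`, `seed`.
#' @export
cross_validate <- function(features, spec, n_folds = 10L, seed = 1L) {
  stopifnot(inherits(features, "feature_matrix"), inherits(spec, "model_spec"))
  labels <- features$labels
  fold <- withr::with_seed(seed,
                           stratified_folds(labels, n_folds, features$subjects))
  per_fold <- vector("list", n_folds)
  pooled_scores <- numeric(length(labels))
  pooled_pred <- integer(length(labels))
  for (f in seq_len(n_folds)) {
    test <- fold == f
    train_feats <- list(x = features$x[!test, , drop = FALSE],
                        labels = labels[!test])
    model <- train_model_spec(spec, train_feats, seed = seed + f)
    pr <- predict_model_spec(model, features$x[test, , drop = FALSE])
    per_fold[[f]] <- counts_from_predictions(labels[test], pr$labels)
    pooled_scores[test] <- pr$scores[, 1L]
    pooled_pred[test] <- pr$labels
  }
  total <- sum_counts(per_fold)
  structure(list(accuracy = accuracy(total),
                 f_measure = f_measure(total),
                 auc = auc(pooled_scores, labels),
                 per_fold = per_fold,
                 counts = total,
                 scheme = "pooled",
                 classifier_id = spec_id(spec),
                 n_folds = as.integer(n_folds),
                 seed = as.integer(seed)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %s (%s, %d-fold CV): accuracy %.2f%%, F %.3f, AUC %.3f\n",
              x$classifier_id, x$scheme, x$n_folds, x$accuracy, x$f_measure,
              x$auc))
  invisible(x)
}

#' Run the per-subject / pooled experiment grid
#'
#' For every classifier specification: one cross-validated report per subject
#' (folding only that subject's trials) and one pooled report with all
#' subjects' trials mixed before folding (the subject-independent protocol;
#' this is pooled-instance CV, not leave-one-subject-out).  Cells whose class
#' counts cannot be stratified are marked skipped rather than failing the run.
#'
#' @param features A [feature_matrix()] with subject codes.
#' @param specs List of [model_spec()] objects.
#' @param n_folds Folds per cell.
#' @param seed Integer seed.
#' @return Object of class `experiment_grid`: list of cells, each with
#'   `subject` (`"ALL"` for pooled), `classifier_id` and either `report` or
#'   `skipped` (the error message).  `summary()` renders the result table.
#' @export
run_experiment_grid <- function(features, specs, n_folds = 10L, seed = 1L) {
  stopifnot(inherits(features, "feature_matrix"))
  if (inherits(specs, "model_spec")) specs <- list(specs)
  subjects <- c(sort(unique(features$subjects)), "ALL")
  cells <- list()
  for (spec in specs) {
    for (subj in subjects) {
      keep <- if (subj == "ALL") rep(TRUE, length(features$subjects))
              else features$subjects == subj
      sub_feats <- feature_matrix(features$x[keep, , drop = FALSE],
                                  features$labels[keep],
                                  features$subjects[keep])
      cell <- list(subject = subj, classifier_id = spec_id(spec))
      res <- tryCatch(cross_validate(sub_feats, spec, n_folds = n_folds,
                                     seed = seed),
                      error = function(e) conditionMessage(e))
      if (inherits(res, "eval_report")) {
        res$scheme <- if (subj == "ALL") "pooled" else "per_subject"
        cell$report <- res
      } else {
        cell$skipped <- res
      }
      cells[[length(cells) + 1L]] <- cell
    }
  }
  structure(list(cells = cells, n_folds = as.integer(n_folds),
                 seed = as.integer(seed)),
            class = "experiment_grid")
}

#' @export
summary.experiment_grid <- function(object, ...) {
  rows <- lapply(object$cells, function(cell) {
    if (!is.null(cell$skipped)) {
      data.frame(subject = cell$subject, classifier = cell$classifier_id,
                 accuracy = NA_real_, f_measure = NA_real_, auc = NA_real_,
                 status = "skipped", stringsAsFactors = FALSE)
    } else {
      r <- cell$report
      data.frame(subject = cell$subject, classifier = cell$classifier_id,
                 accuracy = r$accuracy, f_measure = r$f_measure, auc = r$auc,
                 status = "ok", stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' @export
print.experiment_grid <- function(x, ...) {
  df <- summary(x)
  cat(sprintf("<experiment_grid> %d cells, %d-fold CV, seed %d\n",
              nrow(df), x$n_folds, x$seed))
  print(df, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Write an experiment grid to JSON and a delimited summary table
#'
#' @param grid An `experiment_grid`.
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
write_experiment_grid <- function(grid, dir) {
  stopifnot(inherits(grid, "experiment_grid"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  df <- summary(grid)
  data.table::fwrite(df, file.path(dir, "summary.csv"), quote = FALSE)
  cells <- lapply(grid$cells, function(cell) {
    if (!is.null(cell$skipped)) {
      list(subject = cell$subject, classifier = cell$classifier_id,
           skipped = cell$skipped)
    } else {
      r <- cell$report
      list(subject = cell$subject, classifier = cell$classifier_id,
           scheme = r$scheme, accuracy = r$accuracy, f_measure = r$f_measure,
           auc = r$auc,
           per_fold = lapply(r$per_fold, function(cc) cc[c("tp", "tn", "fp", "fn")]))
    }
  })
  jsonlite::write_json(list(n_folds = grid$n_folds, seed = grid$seed,
                            cells = cells),
                       file.path(dir, "reports.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}
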