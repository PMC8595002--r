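# Metric oracles (brute-force arithmetic and exhaustive pair counting),
# stratification structure and cross-validation contracts.

test_that("accuracy, F-measure, TPR/FPR match direct arithmetic", {
  expect_equal(accuracy(confusion_counts(5, 5, 0, 0)), 100)
  expect_equal(accuracy(confusion_counts(0, 0, 3, 7)), 0)
  expect_equal(accuracy(confusion_counts(30, 40, 10, 20)), 70)
  expect_equal(f_measure(confusion_counts(10, 0, 0, 0)), 1)
  expect_equal(f_measure(confusion_counts(0, 0, 5, 5)), 0)
  expect_equal(f_measure(confusion_counts(30, 0, 10, 20)), 30 / 45,
               tolerance = 1e-4)
  expect_equal(tpr_fpr(confusion_counts(5, 5, 0, 0)), c(tpr = 1, fpr = 0))
  expect_equal(tpr_fpr(confusion_counts(0, 0, 5, 5)), c(tpr = 0, fpr = 1))
  expect_equal(tpr_fpr(confusion_counts(30, 40, 10, 20)),
               c(tpr = 0.6, fpr = 0.2))
  expect_error(accuracy(confusion_counts(0, 0, 0, 0)), "zero total")
  expect_warning(expect_equal(f_measure(confusion_counts(0, 5, 0, 0)), 0),
                 "degenerate")
  expect_error(tpr_fpr(confusion_counts(0, 1, 0, 0)), "TPR")
})

test_that("metrics agree with brute-force arithmetic on 1000 random tables", {
  withr::with_seed(95L, {
    for (i in seq_len(1000L)) {
      v <- stats::rpois(4, 8)
      cc <- confusion_counts(v[1], v[2], v[3], v[4])
      tot <- sum(v)
      if (tot > 0) {
        expect_equal(accuracy(cc), 100 * (v[1] + v[2]) / tot, tolerance = 1e-12)
      }
      if (v[1] + v[3] + v[4] > 0) {
        expect_equal(suppressWarnings(f_measure(cc)),
                     v[1] / (v[1] + (v[3] + v[4]) / 2), tolerance = 1e-12)
      }
    }
  })
})

pair_count_auc <- function(scores, labels) {
  pos <- which(labels == 1L)
  neg <- which(labels == 2L)
  won <- 0
  for (i in pos) for (j in neg) {
    won <- won + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  }
  won / (length(pos) * length(neg))
}

test_that("AUC equals exhaustive pair counting, including ties", {
  expect_equal(auc(c(0.9, 0.8, 0.4, 0.3), c(1L, 2L, 1L, 2L)),
               pair_count_auc(c(0.9, 0.8, 0.4, 0.3), c(1L, 2L, 1L, 2L)))
  expect_equal(auc(c(1, 1, 0, 0), c(1L, 1L, 2L, 2L)), 1)
  expect_equal(auc(rep(0.5, 10), rep(c(1L, 2L), 5)), 0.5)
  withr::with_seed(96L, {
    for (i in seq_len(60L)) {
      n <- sample(4:30, 1)
      labels <- c(1L, 2L, sample(c(1L, 2L), n - 2, replace = TRUE))
      scores <- round(stats::runif(n), 1)  # coarse grid forces ties
      expect_equal(auc(scores, labels), pair_count_auc(scores, labels),
                   tolerance = 1e-12)
    }
  })
  expect_error(auc(c(0.1, 0.2), c(1L, 1L)), "both classes")
})

test_that("stratified folds partition the data with exact class balance", {
  labels <- rep(c(1L, 2L), each = 700L)
  fold <- withr::with_seed(97L, stratified_folds(labels, 10L))
  expect_setequal(unique(fold), 1:10)
  for (f in 1:10) {
    expect_identical(sum(fold == f & labels == 1L), 70L)
    expect_identical(sum(fold == f & labels == 2L), 70L)
  }
  expect_error(stratified_folds(rep(c(1L, 2L), c(5L, 20L)), 10L), "stratify")
})

test_that("cross_validate is deterministic and internally consistent", {
  fm <- blob_features(n = 80L, sep = 1.5, seed = 98L)
  sp <- model_spec(base_learner_spec("knn"), "random_subspace",
                   random_subspace_config(n_members = 5L))
  r1 <- cross_validate(fm, sp, n_folds = 10L, seed = 99L)
  r2 <- cross_validate(fm, sp, n_folds = 10L, seed = 99L)
  expect_identical(r1, r2)
  expect_length(r1$per_fold, 10L)
  # report accuracy equals the value recomputed from summed fold counts
  total <- Reduce(function(a, b) confusion_counts(a$tp + b$tp, a$tn + b$tn,
                                                  a$fp + b$fp, a$fn + b$fn),
                  r1$per_fold)
  expect_equal(r1$accuracy, accuracy(total), tolerance = 1e-9)
  # pooled accuracy equals the instance-weighted mean of fold accuracies
  fold_n <- vapply(r1$per_fold, function(cc) cc$tp + cc$tn + cc$fp + cc$fn,
                   integer(1))
  fold_acc <- vapply(r1$per_fold, accuracy, numeric(1))
  expect_equal(r1$accuracy, sum(fold_acc * fold_n) / sum(fold_n),
               tolerance = 1e-9)
})

test_that("a leaked label feature yields a perfect cross-validated report", {
  fm <- blob_features(n = 60L, sep = 0, seed = 100L)
  fm$x[, 7L] <- ifelse(fm$labels == 1L, 0, 1)
  sp <- model_spec(base_learner_spec("rep_tree"), "none")
  r <- cross_validate(fm, sp, n_folds = 10L, seed = 101L)
  expect_equal(r$accuracy, 100)
  expect_equal(r$auc, 1)
})

test_that("experiment grid produces per-subject plus pooled cells and skips gracefully", {
  fm <- blob_features(n = 60L, sep = 2, seed = 102L,
                      subjects = c("SA", "SB"))
  specs <- list(model_spec(base_learner_spec("knn"), "random_subspace",
                           random_subspace_config(n_members = 3L)),
                model_spec(base_learner_spec("rep_tree"), "rotation_forest",
                           rotation_forest_config(n_members = 3L)))
  grid <- run_experiment_grid(fm, specs, n_folds = 10L, seed = 103L)
  df <- summary(grid)
  expect_identical(nrow(df), 6L)  # 2 specs x (2 subjects + ALL)
  expect_setequal(unique(df$subject), c("SA", "SB", "ALL"))
  expect_true(all(df$status == "ok"))
  # single-subject dataset: subject row and ALL row agree
  fm1 <- blob_features(n = 40L, sep = 2, seed = 104L)
  g1 <- run_experiment_grid(fm1, specs[[1L]], n_folds = 10L, seed = 105L)
  d1 <- summary(g1)
  expect_identical(nrow(d1), 2L)
  expect_equal(d1$accuracy[1L], d1$accuracy[2L])
  # too-small subject cell is skipped, not fatal
  fm2 <- blob_features(n = 24L, sep = 2, seed = 106L,
                       subjects = c(rep("SA", 20L), rep("SB", 4L)))
  g2 <- summary(run_experiment_grid(fm2, specs[[1L]], n_folds = 10L,
                                    seed = 107L))
  expect_identical(g2$status[g2$subject == "SB"], "skipped")
  expect_identical(g2$status[g2$subject == "ALL"], "ok")
})

test_that("grid output files are written and re-readable", {
  fm <- blob_features(n = 40L, sep = 2, seed = 108L)
  grid <- run_experiment_grid(
    fm, model_spec(base_learner_spec("knn"), "random_subspace",
                   random_subspace_config(n_members = 3L)),
    n_folds = 10L, seed = 109L)
  dir <- withr::local_tempdir()
  write_experiment_grid(grid, dir)
  expect_true(file.exists(file.path(dir, "summary.csv")))
  js <- jsonlite::read_json(file.path(dir, "reports.json"))
  expect_length(js$cells, 2L)
})
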