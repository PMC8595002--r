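# Ensemble structure: rotation orthonormality, partition arithmetic,
# subspace sizes, identity reductions, member-wise score oracle, persistence.

test_that("rotation matrices are blockwise orthonormal", {
  fm <- blob_features(n = 50L, seed = 71L)
  m <- train_rotation_forest(rotation_forest_config(n_members = 5L, seed = 72L),
                             base_learner_spec("knn"), fm)
  for (mem in m$members) {
    R <- mem$rotation
    expect_identical(dim(R), c(95L, 95L))
    expect_lt(max(abs(crossprod(R) - diag(95L))), 1e-8)
    # applying R then t(R) restores features
    expect_lt(max(abs(fm$x %*% R %*% t(R) - fm$x)), 1e-8)
  }
})

test_that("feature partition arithmetic: ceil(95/3) = 32 groups, last of size 2", {
  fm <- blob_features(n = 40L, seed = 73L)
  cfg <- rotation_forest_config(n_members = 1L, group_size = 3L, seed = 74L)
  # reproduce the member's partition from the seeded stream
  groups <- withr::with_seed(cfg$seed, split(sample.int(95L),
    rep(seq_len(ceiling(95 / 3)), each = 3L, length.out = 95L)))
  expect_length(groups, 32L)
  sizes <- lengths(groups)
  expect_identical(sum(sizes == 3L), 31L)
  expect_identical(sum(sizes == 2L), 1L)
  expect_setequal(unlist(groups), 1:95)
  expect_error(train_rotation_forest(
    rotation_forest_config(group_size = 96L), base_learner_spec("knn"), fm),
    "group_size")
})

test_that("random-subspace members see duplicate-free subsets of size B", {
  fm <- blob_features(n = 40L, seed = 75L)
  m <- train_random_subspace(random_subspace_config(n_members = 8L,
                                                    subspace_fraction = 0.5,
                                                    seed = 76L),
                             base_learner_spec("knn"), fm)
  for (mem in m$members) {
    expect_length(mem$subset, 47L)  # floor(0.5 * 95)
    expect_identical(anyDuplicated(mem$subset), 0L)
  }
  expect_error(train_random_subspace(
    random_subspace_config(subspace_fraction = 0.001),
    base_learner_spec("knn"), fm), "B < 1")
})

test_that("RSM with fraction 1 and one member equals the bare base learner", {
  fm <- blob_features(n = 60L, sep = 1, seed = 77L)
  te <- blob_features(n = 30L, sep = 1, seed = 78L)
  for (kind in c("knn", "rep_tree", "svm")) {
    ens <- train_random_subspace(
      random_subspace_config(n_members = 1L, subspace_fraction = 1, seed = 5L),
      base_learner_spec(kind), fm)
    bare <- train_base(base_learner_spec(kind), fm, seed = 5L)
    expect_identical(predict_ensemble(ens, te$x)$labels,
                     predict_base(bare, te$x)$labels, label = kind)
  }
})

test_that("single-member full-group rotation forest is a rotated base learner", {
  # raw-distance 1-NN is invariant under any orthogonal rotation, so the
  # single-block RoF must reproduce the bare 1-NN predictions
  fm <- blob_features(n = 60L, sep = 1, seed = 79L)
  te <- blob_features(n = 30L, sep = 1, seed = 80L)
  spec <- base_learner_spec("knn", normalize = FALSE)
  ens <- train_rotation_forest(
    rotation_forest_config(n_members = 1L, group_size = 95L,
                           class_subset_fraction = 1, bootstrap_fraction = 1,
                           seed = 6L),
    spec, fm)
  bare <- train_base(spec, fm, seed = 6L)
  expect_identical(predict_ensemble(ens, te$x)$labels,
                   predict_base(bare, te$x)$labels)
})

test_that("ensemble scores are the mean of member scores and sum to 1", {
  fm <- blob_features(n = 50L, sep = 1, seed = 81L)
  te <- blob_features(n = 5L, sep = 1, seed = 82L)
  m <- train_rotation_forest(rotation_forest_config(n_members = 4L, seed = 83L),
                             base_learner_spec("rep_tree"), fm)
  pr <- predict_ensemble(m, te$x)
  hand <- Reduce(`+`, lapply(m$members, function(mem) {
    predict_base(mem$fit, te$x %*% mem$rotation)$scores
  })) / length(m$members)
  expect_equal(unname(pr$scores), unname(hand), tolerance = 1e-12)
  expect_true(all(abs(rowSums(pr$scores) - 1) < 1e-9))
})

test_that("majority vote is unanimous when every member is perfect", {
  fm <- blob_features(n = 60L, sep = 8, seed = 84L)
  m <- train_random_subspace(random_subspace_config(n_members = 11L,
                                                    subspace_fraction = 0.9,
                                                    seed = 85L),
                             base_learner_spec("knn"), fm)
  pr <- predict_ensemble(m, fm)
  expect_identical(pr$labels, fm$labels)
})

test_that("training on its own training set recovers labels (1-NN base)", {
  fm <- blob_features(n = 40L, sep = 0.3, seed = 86L)
  m <- train_rotation_forest(rotation_forest_config(n_members = 3L, seed = 87L),
                             base_learner_spec("knn"), fm)
  expect_identical(predict_ensemble(m, fm)$labels, fm$labels)
})

test_that("ensembles are deterministic and survive a save/load round trip", {
  fm <- blob_features(n = 50L, sep = 1, seed = 88L)
  te <- blob_features(n = 20L, sep = 1, seed = 89L)
  a <- train_random_subspace(random_subspace_config(n_members = 5L, seed = 90L),
                             base_learner_spec("c45_like"), fm)
  b <- train_random_subspace(random_subspace_config(n_members = 5L, seed = 90L),
                             base_learner_spec("c45_like"), fm)
  expect_identical(predict_ensemble(a, te$x), predict_ensemble(b, te$x))
  dir <- withr::local_tempdir()
  save_model(a, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  c <- load_model(dir)
  expect_identical(predict_ensemble(c, te$x), predict_ensemble(a, te$x))
})

test_that("prediction rejects width mismatches", {
  fm <- blob_features(n = 30L, seed = 91L)
  m <- train_random_subspace(random_subspace_config(n_members = 2L, seed = 92L),
                             base_learner_spec("knn"), fm)
  expect_error(predict_ensemble(m, fm$x[, 1:10]), "width")
})
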