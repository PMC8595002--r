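# Container validation and file round trips (delimited and EDF).

test_that("segment and dataset invariants are enforced", {
  m <- matrix(stats::rnorm(3 * 64), 3, 64)
  expect_error(eeg_segment(m, rate = 0, label = 1L), "rate")
  expect_error(eeg_segment(m, rate = 100, label = 3L), "label")
  expect_error(eeg_segment(m, rate = 100, label = 1L,
                           channel_names = c("a", "b")), "channel_names")
  expect_error(eeg_segment(m[, 1:20], rate = 100, label = 1L), "at least 32")
  s1 <- eeg_segment(m, rate = 100, label = 1L)
  s2 <- eeg_segment(m, rate = 200, label = 2L)
  expect_error(eeg_dataset(list(s1, s2)), "rate")
  expect_error(eeg_dataset(list()), "at least one")
  ds <- eeg_dataset(list(s1, eeg_segment(m, 100, 2L)))
  expect_identical(dataset_labels(ds), c(1L, 2L))
})

test_that("delimited round trip is the identity on an EEG dataset", {
  ds <- tiny_dataset(seed = 11L, trials_per_class_per_subject = 2L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_segments(ds, path)
  back <- read_segments(path)
  expect_identical(length(back), length(ds))
  expect_identical(dataset_labels(back), dataset_labels(ds))
  expect_identical(dataset_subjects(back), dataset_subjects(ds))
  for (i in seq_along(ds$segments)) {
    expect_identical(back$segments[[i]]$samples, ds$segments[[i]]$samples)
  }
})

test_that("delimited reader rejects malformed dumps", {
  ds <- tiny_dataset(seed = 12L, trials_per_class_per_subject = 1L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_segments(ds, path)
  # corrupt the label of one trial to an out-of-set value
  txt <- readLines(path)
  txt <- sub("^1,S01,1,", "1,S01,3,", txt)
  writeLines(txt, path)
  expect_error(read_segments(path), "labels must be in \\{1, 2\\}")
  expect_error(read_segments(file.path(tempdir(), "nope.csv")), "not found")
})

test_that("writing an empty dataset is refused", {
  ds <- tiny_dataset(seed = 13L, trials_per_class_per_subject = 1L)
  ds$segments <- list()
  expect_error(write_segments(ds, tempfile()), "empty")
})

test_that("EDF round trip preserves labels exactly and samples to 16-bit", {
  ds <- tiny_dataset(seed = 14L, trials_per_class_per_subject = 5L)
  path <- withr::local_tempfile(fileext = ".edf")
  write_segments(ds, path, format = "edf")
  back <- read_segments(path, format = "edf")
  expect_identical(length(back), 10L)
  expect_identical(dataset_labels(back), dataset_labels(ds))
  expect_identical(dataset_subjects(back), dataset_subjects(ds))
  expect_equal(back$segments[[1L]]$rate, 100)
  # quantization error bounded by one digital step of the per-channel range
  all_samples <- do.call(cbind, lapply(ds$segments, `[[`, "samples"))
  step <- apply(all_samples, 1L, function(r) diff(range(r))) / 65535
  for (i in seq_along(ds$segments)) {
    err <- abs(ds$segments[[i]]$samples - back$segments[[i]]$samples)
    expect_true(all(err <= matrix(step, nrow = 3,
                                  ncol = ncol(err)) + 1e-12))
  }
})

test_that("feature table round trip is bit-exact", {
  fm <- blob_features(n = 20L, seed = 3L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(fm, path)
  lines <- readLines(path)
  expect_length(lines, 21L)  # header + 20 rows
  back <- read_feature_table(path)
  expect_identical(back$x, fm$x)
  expect_identical(back$labels, fm$labels)
  expect_identical(back$subjects, fm$subjects)
})

test_that("feature matrix contracts are enforced", {
  x <- matrix(0, 4, 96)
  expect_error(feature_matrix(x, rep(1:2, 2), rep("S", 4)), "95")
  x <- matrix(0, 4, 95)
  expect_error(feature_matrix(x, rep(1:2, 3), rep("S", 4)), "must agree")
  x[1, 1] <- NA
  expect_error(feature_matrix(x, rep(1:2, 2), rep("S", 4)), "finite")
})

test_that("canonical feature header is fixed and reproducible", {
  expect_length(feature_names(), 95L)
  expect_identical(feature_names()[1:6],
                   c("sb01_mav", "sb01_pow", "sb01_std", "sb01_skew",
                     "sb01_kurt", "sb02_mav"))
  expect_identical(feature_names()[81], "ratio_01")
  expect_identical(feature_names(), feature_names())
})
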