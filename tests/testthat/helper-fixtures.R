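# Shared fixtures: tiny deterministic datasets and configs, built in code.

# internal helpers exercised directly by white-box tests
dwt_forward <- mieeg:::dwt_forward
dwt_inverse <- mieeg:::dwt_inverse
dwt_step <- mieeg:::dwt_step
colored_noise <- mieeg:::colored_noise
tree_n_nodes <- mieeg:::tree_n_nodes
stratified_folds <- mieeg:::stratified_folds
train_model_spec <- mieeg:::train_model_spec

tiny_config <- function(seed = 101L, ...) {
  args <- utils::modifyList(
    list(n_subjects = 1L, trials_per_class_per_subject = 3L,
         rate = 100, duration = 3.5, seed = seed),
    list(...))
  do.call(simulation_config, args)
}

tiny_dataset <- function(seed = 101L, ...) {
  generate_dataset(tiny_config(seed = seed, ...))
}

# small separable two-blob feature matrix (95 columns, first dims informative)
blob_features <- function(n = 60L, sep = 3, seed = 7L, subjects = "S1") {
  withr::with_seed(seed, {
    y <- rep(c(1L, 2L), length.out = n)
    x <- matrix(stats::rnorm(n * 95L, sd = 0.5), n, 95L)
    x[y == 2L, 1:5] <- x[y == 2L, 1:5] + sep
    # contiguous subject blocks so every subject sees both classes
    subj <- rep(subjects, each = ceiling(n / length(subjects)))[seq_len(n)]
    feature_matrix(x, y, subj)
  })
}

random_segment <- function(n = 350L, nch = 3L, seed = 5L, rate = 100) {
  withr::with_seed(seed,
    eeg_segment(matrix(stats::rnorm(nch * n), nch, n), rate = rate,
                label = 1L, subject = "S1"))
}
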