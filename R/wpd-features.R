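# 95-dimensional statistical descriptor of one trial: 16 level-4 wavelet
# packet subbands x {MAV, average power, standard deviation, skewness,
# kurtosis} = 80 statistics, plus the 15 adjacent-subband MAV ratios.

#' Feature extraction configuration
#'
#' @param wavelet A [wavelet_spec()] with `level = 4` (16 subbands).
#' @param channel_aggregation How three channels become one 95-vector:
#'   `"mean"` decomposes each channel and averages every feature across
#'   channels; `"concat_signal"` joins the channels end-to-end before one
#'   decomposition; `"single_channel"` analyses the channel named in
#'   `channel`.
#' @param channel Channel name used by `"single_channel"` (default: first
#'   channel of the segment).
#' @param std_divisor `"n_minus_1"` (sample standard deviation, default) or
#'   `"n"`.
#' @param kurtosis_convention `"pearson"` (normal -> 3, default) or
#'   `"excess"` (normal -> 0).
#' @param ratio_epsilon Additive guard on ratio denominators so all 15 ratios
#'   are finite even for all-zero subbands.
#' @return Object of class `feature_config`.
#' @export
feature_config <- function(wavelet = wavelet_spec("db", 4L, 4L),
                           channel_aggregation = c("mean", "concat_signal",
                                                   "single_channel"),
                           channel = NULL,
                           std_divisor = c("n_minus_1", "n"),
                           kurtosis_convention = c("pearson", "excess"),
                           ratio_epsilon = 1e-12) {
  channel_aggregation <- match.arg(channel_aggregation)
  std_divisor <- match.arg(std_divisor)
  kurtosis_convention <- match.arg(kurtosis_convention)
  stopifnot(inherits(wavelet, "wavelet_spec"))
  if (!is.numeric(ratio_epsilon) || ratio_epsilon <= 0) {
    stop("ratio_epsilon must be a positive real")
  }
  structure(list(wavelet = wavelet, channel_aggregation = channel_aggregation,
                 channel = channel, std_divisor = std_divisor,
                 kurtosis_convention = kurtosis_convention,
                 ratio_epsilon = ratio_epsilon),
            class = "feature_config")
}

#' Five subband statistics
#'
#' MAV (mean absolute value), average power (mean square), standard deviation
#' (configurable divisor), skewness (third standardized moment) and kurtosis
#' (Pearson or excess).  Zero-variance blocks return 0 for skewness and
#' kurtosis by convention, so every feature is always finite.
#'
#' @param block Numeric vector of coefficients, length >= 1.
#' @param config A [feature_config()].
#' @return Named numeric vector `c(mav, pow, std, skew, kurt)`.
#' @export
subband_stats <- function(block, config = feature_config()) {
  n <- length(block)
  if (n == 0L) stop("empty coefficient block")
  mav <- mean(abs(block))
  pow <- mean(block^2)
  mu <- mean(block)
  m2 <- mean((block - mu)^2)
  sdv <- if (n > 1L && config$std_divisor == "n_minus_1") {
    sqrt(m2 * n / (n - 1L))
  } else {
    sqrt(m2)
  }
  if (m2 < .Machine$double.eps * max(1, pow)) {
    skew <- 0
    kurt <- 0
  } else {
    skew <- mean((block - mu)^3) / m2^1.5
    kurt <- mean((block - mu)^4) / m2^2
    if (config$kurtosis_convention == "excess") kurt <- kurt - 3
  }
  c(mav = mav, pow = pow, std = sdv, skew = skew, kurt = kurt)
}

#' Adjacent-subband MAV ratios
#'
#' For blocks in canonical (natural filter-bank) order,
#' `ratio_i = MAV(block i) / (MAV(block i + 1) + ratio_epsilon)`, i = 1..15.
#'
#' @param subbands A `subband_set` with exactly 16 blocks.
#' @param config A [feature_config()].
#' @return Numeric vector of length 15.
#' @export
adjacent_ratios <- function(subbands, config = feature_config()) {
  stopifnot(inherits(subbands, "subband_set"))
  nb <- length(subbands$blocks)
  if (nb != 16L) stop("adjacent ratios are defined for 16 subbands, got ", nb)
  mavs <- vapply(subbands$blocks, function(b) mean(abs(b)), numeric(1))
  mavs[1:15] / (mavs[2:16] + config$ratio_epsilon)
}

features_of_signal <- function(signal, config) {
  sb <- wpd_decompose(signal, config$wavelet)
  stats <- vapply(sb$blocks, subband_stats, numeric(5), config = config)
  c(as.vector(stats), adjacent_ratios(sb, config))
}

#' Extract the 95-dimensional feature vector of one trial
#'
#' @param segment An [eeg_segment()] (denoised or raw).
#' @param config A [feature_config()].
#' @return Object of class `feature_vector`: numeric vector of length 95 with
#'   canonical names, plus `label` and `subject` attributes.
#' @export
extract_features <- function(segment, config = feature_config()) {
  stopifnot(inherits(segment, "eeg_segment"), inherits(config, "feature_config"))
  v <- switch(config$channel_aggregation,
    mean = {
      per_ch <- vapply(seq_len(nrow(segment$samples)),
                       function(ch) features_of_signal(segment$samples[ch, ], config),
                       numeric(95))
      rowMeans(per_ch)
    },
    concat_signal = features_of_signal(as.vector(t(segment$samples)), config),
    single_channel = {
      ch <- config$channel
      if (is.null(ch)) ch <- segment$channel_names[1L]
      idx <- match(ch, segment$channel_names)
      if (is.na(idx)) stop("channel '", ch, "' not present in segment")
      features_of_signal(segment$samples[idx, ], config)
    })
  names(v) <- feature_names()
  if (!all(is.finite(v))) stop("non-finite feature encountered")
  structure(v, label = segment$label, subject = segment$subject,
            class = "feature_vector")
}

#' Extract features for every trial of a dataset
#'
#' @param dataset An [eeg_dataset()].
#' @param config A [feature_config()].
#' @return A [feature_matrix()] with labels and subject codes carried through
#'   in dataset order.
#' @export
extract_feature_matrix <- function(dataset, config = feature_config()) {
  stopifnot(inherits(dataset, "eeg_dataset"))
  n <- length(dataset$segments)
  x <- matrix(0, nrow = n, ncol = 95L)
  for (i in seq_len(n)) {
    x[i, ] <- tryCatch(as.numeric(extract_features(dataset$segments[[i]], config)),
                       error = function(e) {
                         stop("feature extraction failed at trial ", i, ": ",
                              conditionMessage(e))
                       })
  }
  feature_matrix(x, labels = dataset_labels(dataset),
                 subjects = dataset_subjects(dataset))
}
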