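# Domain containers (trial segment, dataset, feature matrix) and the
# delimited-text readers/writers shared by every pipeline stage.
# Amplitudes are treated as microvolts throughout but never converted;
# the unit is metadata only.

MIN_SEGMENT_SAMPLES <- 32L  # level-5 dyadic analysis needs >= 2^5 samples

.datatable.aware <- TRUE

#' Construct a single labelled EEG trial
#'
#' @param samples Numeric matrix, channels x time, microvolts.
#' @param rate Sampling frequency in Hz (> 0).
#' @param label Class identifier, 1 (right hand) or 2 (right foot).
#' @param subject Subject code.
#' @param channel_names Character vector, one name per matrix row.
#' @return Object of class `eeg_segment`.
#' @export
eeg_segment <- function(samples, rate, label, subject = "S1",
                        channel_names = NULL) {
  if (!is.matrix(samples) || !is.numeric(samples)) {
    stop("samples must be a numeric matrix (channels x time)")
  }
  if (is.null(channel_names)) {
    channel_names <- rownames(samples)
    if (is.null(channel_names)) channel_names <- paste0("CH", seq_len(nrow(samples)))
  }
  if (length(channel_names) != nrow(samples)) {
    stop("channel_names length (", length(channel_names),
         ") must equal the channel count (", nrow(samples), ")")
  }
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0) {
    stop("rate must be a positive scalar (Hz)")
  }
  if (!label %in% c(1L, 2L)) stop("label must be 1 or 2, got: ", label)
  if (ncol(samples) < MIN_SEGMENT_SAMPLES) {
    stop("trial has ", ncol(samples), " samples; at least ",
         MIN_SEGMENT_SAMPLES, " are required for level-5 wavelet analysis")
  }
  rownames(samples) <- channel_names
  structure(list(samples = samples, rate = as.numeric(rate),
                 label = as.integer(label), subject = as.character(subject),
                 channel_names = as.character(channel_names)),
            class = "eeg_segment")
}

#' @export
print.eeg_segment <- function(x, ...) {
  cat(sprintf("<eeg_segment> subject %s, label %d, %d ch x %d samples @ %g Hz\n",
              x$subject, x$label, nrow(x$samples), ncol(x$samples), x$rate))
  invisible(x)
}

#' Construct an EEG dataset
#'
#' Validates that all segments share rate, channel count and channel order and
#' that labels are drawn from \{1, 2\}.
#'
#' @param segments List of [eeg_segment()] objects.
#' @param metadata Free-form named list of provenance information.
#' @return Object of class `eeg_dataset`.
#' @export
eeg_dataset <- function(segments, metadata = list()) {
  if (length(segments) == 0L) stop("a dataset must contain at least one segment")
  if (!all(vapply(segments, inherits, logical(1), "eeg_segment"))) {
    stop("all elements must be eeg_segment objects")
  }
  rate <- segments[[1L]]$rate
  nch <- nrow(segments[[1L]]$samples)
  for (i in seq_along(segments)) {
    s <- segments[[i]]
    if (s$rate != rate) stop("segment ", i, " has rate ", s$rate,
                             ", expected ", rate)
    if (nrow(s$samples) != nch) {
      stop("segment ", i, " has ", nrow(s$samples),
           " channels, expected ", nch)
    }
  }
  labs <- vapply(segments, function(s) s$label, integer(1))
  if (!all(labs %in% c(1L, 2L))) stop("labels must be drawn from {1, 2}")
  structure(list(segments = segments, metadata = metadata),
            class = "eeg_dataset")
}

#' @export
print.eeg_dataset <- function(x, ...) {
  labs <- dataset_labels(x)
  cat(sprintf("<eeg_dataset> %d trials (%d / %d per class), %d channels @ %g Hz, %d subject(s)\n",
              length(x$segments), sum(labs == 1L), sum(labs == 2L),
              nrow(x$segments[[1L]]$samples), x$segments[[1L]]$rate,
              length(unique(dataset_subjects(x)))))
  invisible(x)
}

#' @export
length.eeg_dataset <- function(x) length(x$segments)

#' Labels of all trials in a dataset
#' @param dataset An `eeg_dataset`.
#' @return Integer vector of class labels.
#' @export
dataset_labels <- function(dataset) {
  vapply(dataset$segments, function(s) s$label, integer(1))
}

#' Subject codes of all trials in a dataset
#' @param dataset An `eeg_dataset`.
#' @return Character vector of subject codes.
#' @export
dataset_subjects <- function(dataset) {
  vapply(dataset$segments, function(s) s$subject, character(1))
}

# ---- delimited trial dump ---------------------------------------------------
# Layout: CSV, one row per (trial, channel); columns
#   trial, subject, label, rate, channel, s0001..s<N>
# Values printed with %.17g so a round trip is bit-exact.

#' Write an EEG dataset to disk
#'
#' @param dataset An [eeg_dataset()].
#' @param path Output file path.
#' @param format `"delimited"` (CSV trial dump, lossless) or `"edf"`
#'   (European Data Format, 16-bit quantized; labels carried in an extra
#'   `TRIAL_LABEL` signal, subject codes in a JSON sidecar).
#' @return The path, invisibly.
#' @export
write_segments <- function(dataset, path, format = c("delimited", "edf")) {
  format <- match.arg(format)
  stopifnot(inherits(dataset, "eeg_dataset"))
  if (length(dataset$segments) == 0L) stop("refusing to write an empty dataset")
  if (format == "edf") return(write_edf_segments(dataset, path))
  nsamp <- ncol(dataset$segments[[1L]]$samples)
  if (!all(vapply(dataset$segments, function(s) ncol(s$samples), integer(1)) == nsamp)) {
    stop("delimited format requires equal-length trials")
  }
  rows <- vector("list", length(dataset$segments))
  for (i in seq_along(dataset$segments)) {
    s <- dataset$segments[[i]]
    m <- s$samples
    dt <- data.table::data.table(
      trial = i, subject = s$subject, label = s$label, rate = s$rate,
      channel = s$channel_names)
    vals <- data.table::as.data.table(
      matrix(sprintf("%.17g", t(m)), nrow = nrow(m), byrow = TRUE))
    data.table::setnames(vals, sprintf("s%04d", seq_len(nsamp)))
    rows[[i]] <- cbind(dt, vals)
  }
  out <- data.table::rbindlist(rows)
  data.table::fwrite(out, path, quote = FALSE)
  meta <- dataset$metadata
  if (length(meta) > 0L) {
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Read an EEG dataset from disk
#'
#' @param path File written by [write_segments()].
#' @param format `"delimited"` or `"edf"`.
#' @return An [eeg_dataset()].
#' @export
read_segments <- function(path, format = c("delimited", "edf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "edf") return(read_edf_segments(path))
  dt <- data.table::fread(path, header = TRUE)
  need <- c("trial", "subject", "label", "rate", "channel")
  if (!all(need %in% names(dt))) {
    stop("malformed trial dump: missing columns ",
         paste(setdiff(need, names(dt)), collapse = ", "))
  }
  scols <- grep("^s[0-9]+$", names(dt), value = TRUE)
  if (length(scols) == 0L) stop("malformed trial dump: no sample columns")
  ids <- unique(dt$trial)
  nch <- NULL
  segs <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    block <- dt[dt$trial == ids[k], ]
    if (!is.null(nch) && nrow(block) != nch) {
      stop("trial ", ids[k], " has ", nrow(block),
           " channels; expected ", nch)
    }
    nch <- nrow(block)
    lab <- unique(block$label)
    if (length(lab) != 1L) stop("trial ", ids[k], " has inconsistent labels")
    if (!lab %in% c(1, 2)) {
      stop("trial ", ids[k], " carries label ", lab, "; labels must be in {1, 2}")
    }
    m <- as.matrix(block[, scols, with = FALSE])
    storage.mode(m) <- "double"
    dimnames(m) <- NULL
    segs[[k]] <- eeg_segment(m, rate = block$rate[1L], label = lab,
                             subject = block$subject[1L],
                             channel_names = block$channel)
  }
  meta <- list()
  side <- paste0(path, ".json")
  if (file.exists(side)) meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  eeg_dataset(segs, metadata = meta)
}

# ---- feature tables ---------------------------------------------------------

#' Canonical names of the 95 features
#'
#' Order: subbands 1..16, each contributing `mav`, `pow`, `std`, `skew`,
#' `kurt`, followed by the 15 adjacent-subband MAV ratios.
#'
#' @return Character vector of length 95.
#' @export
feature_names <- function() {
  stats <- c("mav", "pow", "std", "skew", "kurt")
  c(as.vector(t(outer(sprintf("sb%02d", 1:16), stats, paste, sep = "_"))),
    sprintf("ratio_%02d", 1:15))
}

#' Construct a feature matrix
#'
#' @param x Numeric matrix, trials x 95, columns in canonical order.
#' @param labels Integer class labels, one per row.
#' @param subjects Character subject codes, one per row.
#' @return Object of class `feature_matrix`.
#' @export
feature_matrix <- function(x, labels, subjects) {
  if (!is.matrix(x) || !is.numeric(x)) stop("x must be a numeric matrix")
  if (ncol(x) != 95L) {
    stop("a feature matrix must have exactly 95 columns, got ", ncol(x))
  }
  if (nrow(x) != length(labels) || nrow(x) != length(subjects)) {
    stop("row count (", nrow(x), "), label count (", length(labels),
         ") and subject count (", length(subjects), ") must agree")
  }
  if (!all(labels %in% c(1L, 2L))) stop("labels must be drawn from {1, 2}")
  if (!all(is.finite(x))) stop("feature matrix contains non-finite entries")
  colnames(x) <- feature_names()
  structure(list(x = x, labels = as.integer(labels),
                 subjects = as.character(subjects)),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d trials x %d features, %d subject(s)\n",
              nrow(x$x), ncol(x$x), length(unique(x$subjects))))
  invisible(x)
}

#' Write a feature table as delimited text
#'
#' Header row carries the canonical feature names plus `label` and `subject`;
#' values are printed with 17 significant digits so parsing the file back
#' reproduces them bit-for-bit.
#'
#' @param matrix A [feature_matrix()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_feature_table <- function(matrix, path) {
  stopifnot(inherits(matrix, "feature_matrix"))
  chr <- data.table::as.data.table(
    matrix(sprintf("%.17g", matrix$x), nrow = nrow(matrix$x)))
  data.table::setnames(chr, feature_names())
  chr[, `:=`(label = matrix$labels, subject = matrix$subjects)]
  data.table::fwrite(chr, path, quote = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path File path.
#' @return A [feature_matrix()].
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, header = TRUE)
  fn <- feature_names()
  if (!all(fn %in% names(dt)) || !all(c("label", "subject") %in% names(dt))) {
    stop("malformed feature table: expected the 95 canonical feature columns",
         " plus 'label' and 'subject'")
  }
  x <- as.matrix(dt[, fn, with = FALSE])
  storage.mode(x) <- "double"
  feature_matrix(x, labels = dt$label, subjects = as.character(dt$subject))
}
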