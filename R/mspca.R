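# Multiscale PCA denoising: a 5-level Daubechies pyramid per channel, PCA
# across channels on the coefficient matrix of every scale, eigenvalue-based
# component retention, wavelet synthesis.

#' MSPCA configuration
#'
#' @param wavelet A [wavelet_spec()]; the denoiser uses a level-5 Daubechies
#'   pyramid by default.
#' @param retention_rule `"kaiser"` (keep components with eigenvalue above the
#'   mean eigenvalue), `"fixed_k"`, or `"none"` (keep all; the denoiser then
#'   is the identity).
#' @param fixed_k Number of components kept under `"fixed_k"`.
#' @param center Center coefficient matrices before PCA (means restored on
#'   reconstruction, so DC content is preserved).
#' @param process_approximation Also PCA-process the deepest approximation
#'   band; disable for the stricter details-only reading.
#' @return Object of class `mspca_config`.
#' @export
mspca_config <- function(wavelet = wavelet_spec("db", 4L, 5L),
                         retention_rule = c("kaiser", "fixed_k", "none"),
                         fixed_k = NULL, center = TRUE,
                         process_approximation = TRUE) {
  retention_rule <- match.arg(retention_rule)
  stopifnot(inherits(wavelet, "wavelet_spec"))
  if (retention_rule == "fixed_k" &&
      (is.null(fixed_k) || fixed_k < 1 || fixed_k != round(fixed_k))) {
    stop("retention_rule 'fixed_k' requires a positive integer fixed_k")
  }
  structure(list(wavelet = wavelet, retention_rule = retention_rule,
                 fixed_k = if (is.null(fixed_k)) NULL else as.integer(fixed_k),
                 center = isTRUE(center),
                 process_approximation = isTRUE(process_approximation)),
            class = "mspca_config")
}

#' PCA of a data matrix via its covariance eigendecomposition
#'
#' Covariance uses the n - 1 divisor; scores are the (centered) data projected
#' on the loadings; with all components retained the residual is zero and
#' `scores %*% t(loadings)` reproduces the centered input.
#'
#' @param X Numeric matrix, observations x variables, >= 2 rows.
#' @param center Subtract column means first (default `TRUE`).
#' @return Object of class `pca_result` with `loadings`, `scores`,
#'   `eigenvalues` (non-increasing), `n_retained`, `residual`, `center`.
#' @export
pca_decompose <- function(X, center = TRUE) {
  if (!is.matrix(X)) X <- as.matrix(X)
  if (nrow(X) < 2L) stop("PCA needs at least 2 observations (covariance undefined)")
  if (ncol(X) < 1L) stop("PCA needs at least 1 variable")
  mu <- if (center) colMeans(X) else numeric(ncol(X))
  Xc <- sweep(X, 2L, mu)
  C <- crossprod(Xc) / (nrow(X) - 1L)
  e <- eigen(C, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  P <- e$vectors
  T <- Xc %*% P
  structure(list(loadings = P, scores = T, eigenvalues = lam,
                 n_retained = ncol(X),
                 residual = matrix(0, nrow(X), ncol(X)),
                 center = mu),
            class = "pca_result")
}

#' Select the retained principal components
#'
#' `"kaiser"` keeps components with eigenvalue strictly above the mean
#' eigenvalue (at least one is always kept: when all eigenvalues tie, the
#' first component is retained so the model is never empty); `"fixed_k"`
#' keeps exactly `fixed_k`; `"none"` keeps all.
#'
#' @param result A [pca_decompose()] result.
#' @param rule Retention rule.
#' @param fixed_k Component count for `"fixed_k"`.
#' @return The `pca_result` with `n_retained` and `residual` updated.
#' @export
retain_components <- function(result, rule = c("kaiser", "fixed_k", "none"),
                              fixed_k = NULL) {
  rule <- match.arg(rule)
  stopifnot(inherits(result, "pca_result"))
  p <- length(result$eigenvalues)
  A <- switch(rule,
    none = p,
    fixed_k = {
      if (is.null(fixed_k) || fixed_k < 1 || fixed_k > p) {
        stop("fixed_k must lie in 1..", p)
      }
      as.integer(fixed_k)
    },
    kaiser = {
      k <- sum(result$eigenvalues > mean(result$eigenvalues))
      if (k == 0L) 1L else k
    })
  result$n_retained <- A
  keep <- seq_len(A)
  recon <- result$scores[, keep, drop = FALSE] %*%
    t(result$loadings[, keep, drop = FALSE])
  centered <- result$scores %*% t(result$loadings)
  result$residual <- centered - recon
  result
}

#' Reconstruction from the retained components
#' @param result A `pca_result` (after [retain_components()]).
#' @return Matrix of the same shape as the PCA input.
#' @export
pca_reconstruct <- function(result) {
  stopifnot(inherits(result, "pca_result"))
  keep <- seq_len(result$n_retained)
  sweep(result$scores[, keep, drop = FALSE] %*%
          t(result$loadings[, keep, drop = FALSE]),
        2L, result$center, `+`)
}

#' Multiscale PCA denoising of one trial
#'
#' Each channel is decomposed with a level-`L` Daubechies pyramid; at every
#' scale the coefficient-by-channel matrix (details D1..DL, and the deepest
#' approximation if `process_approximation`) is replaced by its
#' retained-component PCA reconstruction; channels are then resynthesized.
#' With `retention_rule = "none"` the operation is the identity to machine
#' precision.  Single-channel input is passed through with a warning (PCA
#' across one variable is the identity).
#'
#' @param segment An [eeg_segment()].
#' @param config An [mspca_config()].
#' @return A denoised [eeg_segment()] of identical shape, rate, label, subject.
#' @export
denoise <- function(segment, config) {
  stopifnot(inherits(segment, "eeg_segment"), inherits(config, "mspca_config"))
  n <- ncol(segment$samples)
  level <- config$wavelet$level
  if (n < 2L^level) {
    stop("trial of ", n, " samples too short for level-", level, " analysis")
  }
  nch <- nrow(segment$samples)
  if (nch == 1L) {
    warning("single-channel segment: PCA across one variable is the identity; ",
            "returning the input unchanged")
    return(segment)
  }
  decs <- lapply(seq_len(nch),
                 function(ch) dwt_forward(segment$samples[ch, ], config$wavelet))
  process_band <- function(get, set) {
    M <- vapply(decs, get, numeric(length(get(decs[[1L]]))))
    pr <- pca_decompose(M, center = config$center)
    pr <- retain_components(pr, config$retention_rule, config$fixed_k)
    Mhat <- pca_reconstruct(pr)
    for (ch in seq_len(nch)) decs[[ch]] <<- set(decs[[ch]], Mhat[, ch])
  }
  for (j in seq_len(level)) {
    local({
      jj <- j
      process_band(function(d) d$details[[jj]],
                   function(d, v) { d$details[[jj]] <- v; d })
    })
  }
  if (config$process_approximation) {
    process_band(function(d) d$approx, function(d, v) { d$approx <- v; d })
  }
  out <- segment$samples
  for (ch in seq_len(nch)) out[ch, ] <- dwt_inverse(decs[[ch]])
  eeg_segment(out, rate = segment$rate, label = segment$label,
              subject = segment$subject, channel_names = segment$channel_names)
}

#' Denoise every trial of a dataset
#' @param dataset An [eeg_dataset()].
#' @param config An [mspca_config()].
#' @return The denoised [eeg_dataset()].
#' @export
denoise_dataset <- function(dataset, config) {
  stopifnot(inherits(dataset, "eeg_dataset"))
  segs <- vector("list", length(dataset$segments))
  for (i in seq_along(segs)) {
    segs[[i]] <- tryCatch(denoise(dataset$segments[[i]], config),
                          error = function(e) {
                            stop("denoising failed at trial ", i, ": ",
                                 conditionMessage(e))
                          })
  }
  eeg_dataset(segs, metadata = dataset$metadata)
}
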