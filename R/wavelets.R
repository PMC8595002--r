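# Orthogonal Daubechies filter bank and the periodized discrete transforms
# (DWT for the denoiser, full wavelet-packet tree for feature extraction).
#
# Signals whose length is not a multiple of 2^level are zero-padded up to the
# next multiple before analysis and trimmed after synthesis.  Zero padding
# keeps the transform exactly orthogonal on the padded domain, so perfect
# reconstruction, Parseval energy conservation and energy non-expansion under
# coefficient shrinkage all hold to machine precision for any input length.

# Daubechies extremal-phase scaling filters, db1..db10, computed by spectral
# factorization of the maxflat half-band polynomial and checked against the
# orthonormality conditions sum(h) = sqrt(2), <h, h(.-2m)> = delta_m (< 2e-12).
.daub_table <- list(
  c(7.07106781186547573e-01, 7.07106781186547573e-01),
  c(4.82962913144534156e-01, 8.36516303737807831e-01, 2.24143868042013417e-01,
    -1.29409522551260397e-01),
  c(3.32670552950082854e-01, 8.06891509311093214e-01, 4.59877502118491543e-01,
    -1.35011020010255056e-01, -8.54412738820268802e-02, 3.52262918857095472e-02),
  c(2.30377813308896146e-01, 7.14846570552914784e-01, 6.30880767929858588e-01,
    -2.79837694168588343e-02, -1.87034811719092336e-01, 3.08413818355606738e-02,
    3.28830116668851202e-02, -1.05974017850690005e-02),
  c(1.60102397974194510e-01, 6.03829269797195423e-01, 7.24308528437778487e-01,
    1.38428145901318717e-01, -2.42294887066388465e-01, -3.22448695846414696e-02,
    7.75714938400452886e-02, -6.24149021279869851e-03, -1.25807519990821862e-02,
    3.33572528547380377e-03),
  c(1.11540743350109203e-01, 4.94623890398452726e-01, 7.51133908021097585e-01,
    3.15250351709203402e-01, -2.26264693965436442e-01, -1.29766867567265298e-01,
    9.75016055873180187e-02, 2.75228655303038153e-02, -3.15820393174861408e-02,
    5.53842201161357890e-04, 4.77725751094545178e-03, -1.07730108530846376e-03),
  c(7.78520540850092119e-02, 3.96539319481918284e-01, 7.29132090846239533e-01,
    4.69782287405200727e-01, -1.43906003928561094e-01, -2.24036184993879173e-01,
    7.13092192668236674e-02, 8.06126091510805248e-02, -3.80299369350150587e-02,
    -1.65745416306681131e-02, 1.25509985560990599e-02, 4.29577972921289266e-04,
    -1.80164070404746830e-03, 3.53713799974512977e-04),
  c(5.44158422431479938e-02, 3.12871590914536812e-01, 6.75630736297730961e-01,
    5.85354683654400021e-01, -1.58291052567407844e-02, -2.84015542962032241e-01,
    4.72484573850985676e-04, 1.28747426620575006e-01, -1.73693010018498642e-02,
    -4.40882539308447632e-02, 1.39810279174142002e-02, 8.74609404741457687e-03,
    -4.87035299345681041e-03, -3.91740373377221787e-04, 6.75449406451288916e-04,
    -1.17476784124898907e-04),
  c(3.80779473639099308e-02, 2.43834674612779495e-01, 6.04823123690519382e-01,
    6.57288078051571967e-01, 1.33197385824705666e-01, -2.93273783279728140e-01,
    -9.68407832231281129e-02, 1.48540749338258365e-01, 3.07256814793469800e-02,
    -6.76328290614076760e-02, 2.50947114837289805e-04, 2.23616621237019211e-02,
    -4.72320475775922771e-03, -4.28150368246816692e-03, 1.84764688305849340e-03,
    2.30385763523384841e-04, -2.51963188943006761e-04, 3.93473203163204459e-05),
  c(2.66700579005352614e-02, 1.88176800077578810e-01, 5.27201188931553544e-01,
    6.88459039453782395e-01, 2.81172343661432955e-01, -2.49846424326450017e-01,
    -1.95946274377462898e-01, 1.27369340335075076e-01, 9.30573646031717105e-02,
    -7.13941471664571586e-02, -2.94575368220151325e-02, 3.32126740591840650e-02,
    3.60655356692669848e-03, -1.07331754833226555e-02, 1.39535174704326966e-03,
    1.99240529518101986e-03, -6.85856694957958464e-04, -1.16466855129163937e-04,
    9.35886703198619265e-05, -1.32642028944878034e-05)
)

#' Daubechies analysis filter pair
#'
#' Returns the orthonormal scaling (low-pass) and quadrature-mirror wavelet
#' (high-pass) filters of the Daubechies extremal-phase family.
#'
#' @param order Number of vanishing moments, 1 to 10 (db1 = Haar).
#' @return List with numeric vectors `lo` and `hi`, each of length `2 * order`.
#' @export
daubechies_filter <- function(order) {
  if (!is.numeric(order) || length(order) != 1L || order < 1 ||
      order > length(.daub_table) || order != round(order)) {
    stop("Daubechies order must be an integer in 1..", length(.daub_table))
  }
  lo <- .daub_table[[order]]
  L <- length(lo)
  hi <- rev(lo) * (-1)^(seq_len(L) - 1L)
  list(lo = lo, hi = hi)
}

#' Wavelet specification
#'
#' @param family Wavelet family; only `"db"` (Daubechies) is supported.
#' @param order Filter order (vanishing moments), >= 1.
#' @param level Decomposition depth, >= 1 (or 0 for the identity transform in
#'   packet analysis).
#' @return Object of class `wavelet_spec`.
#' @export
wavelet_spec <- function(family = "db", order = 4L, level = 4L) {
  if (!identical(family, "db")) {
    stop("unsupported wavelet family: ", family, " (only 'db' is available)")
  }
  if (level < 0 || level != round(level)) stop("level must be a non-negative integer")
  if (order < 1 || order != round(order)) stop("order must be a positive integer")
  structure(list(family = family, order = as.integer(order),
                 level = as.integer(level)),
            class = "wavelet_spec")
}

#' @export
print.wavelet_spec <- function(x, ...) {
  cat(sprintf("<wavelet_spec> %s%d, level %d\n", x$family, x$order, x$level))
  invisible(x)
}

# one periodized analysis step; n must be even
dwt_step <- function(x, lo, hi) {
  n <- length(x)
  n2 <- n %/% 2L
  k2 <- seq.int(0L, n - 2L, by = 2L)
  a <- numeric(n2)
  d <- numeric(n2)
  for (m in seq_along(lo)) {
    xi <- x[((k2 + m - 1L) %% n) + 1L]
    a <- a + lo[m] * xi
    d <- d + hi[m] * xi
  }
  list(a = a, d = d)
}

# adjoint of dwt_step == inverse (orthonormal filters)
idwt_step <- function(a, d, lo, hi) {
  n2 <- length(a)
  n <- 2L * n2
  x <- numeric(n)
  k2 <- seq.int(0L, n - 2L, by = 2L)
  for (m in seq_along(lo)) {
    pos <- ((k2 + m - 1L) %% n) + 1L
    x[pos] <- x[pos] + lo[m] * a + hi[m] * d
  }
  x
}

pad_to_multiple <- function(x, block) {
  n <- length(x)
  rem <- n %% block
  if (rem == 0L) return(x)
  c(x, numeric(block - rem))
}

# multilevel pyramid DWT: list(details = list(d1..dL), approx, source_length)
dwt_forward <- function(x, wavelet) {
  level <- wavelet$level
  if (level < 1L) stop("DWT level must be >= 1")
  if (length(x) < 2L^level) {
    stop("signal of length ", length(x), " too short for level-", level,
         " analysis (needs >= ", 2L^level, " samples)")
  }
  f <- daubechies_filter(wavelet$order)
  src <- length(x)
  x <- pad_to_multiple(x, 2L^level)
  details <- vector("list", level)
  a <- x
  for (j in seq_len(level)) {
    s <- dwt_step(a, f$lo, f$hi)
    details[[j]] <- s$d
    a <- s$a
  }
  list(details = details, approx = a, source_length = src, wavelet = wavelet)
}

dwt_inverse <- function(decomp) {
  f <- daubechies_filter(decomp$wavelet$order)
  a <- decomp$approx
  for (j in rev(seq_along(decomp$details))) {
    a <- idwt_step(a, decomp$details[[j]], f$lo, f$hi)
  }
  a[seq_len(decomp$source_length)]
}

#' Wavelet packet decomposition
#'
#' Decomposes a signal with the complete binary filter-bank tree of the given
#' depth.  Both the approximation and the detail branch are split at every
#' level, yielding `2^level` terminal coefficient blocks in natural
#' (filter-bank) order: repeated \[low, high\] splitting, so block 1 is the
#' lowest-frequency packet of the natural ordering.
#'
#' @param signal Numeric vector, length >= `2^level`.
#' @param wavelet A [wavelet_spec()]; `level = 4` yields 16 subbands.
#' @return Object of class `subband_set` with fields `blocks` (list of
#'   `2^level` numeric vectors), `ordering`, `wavelet`, `source_length`.
#' @examples
#' sb <- wpd_decompose(sin(2 * pi * 10 * seq(0, 3.49, by = 0.01)),
#'                     wavelet_spec("db", 4, 4))
#' length(sb$blocks)  # 16
#' @export
wpd_decompose <- function(signal, wavelet) {
  if (!is.numeric(signal)) stop("signal must be numeric")
  level <- wavelet$level
  if (length(signal) < 2L^level) {
    stop("signal of length ", length(signal), " too short for level-", level,
         " packet analysis (needs >= ", 2L^level, " samples)")
  }
  src <- length(signal)
  if (level == 0L) {
    return(structure(list(blocks = list(as.numeric(signal)),
                          ordering = "natural", wavelet = wavelet,
                          source_length = src),
                     class = "subband_set"))
  }
  f <- daubechies_filter(wavelet$order)
  x <- pad_to_multiple(as.numeric(signal), 2L^level)
  blocks <- list(x)
  for (j in seq_len(level)) {
    nxt <- vector("list", 2L * length(blocks))
    for (b in seq_along(blocks)) {
      s <- dwt_step(blocks[[b]], f$lo, f$hi)
      nxt[[2L * b - 1L]] <- s$a
      nxt[[2L * b]] <- s$d
    }
    blocks <- nxt
  }
  structure(list(blocks = blocks, ordering = "natural", wavelet = wavelet,
                 source_length = src),
            class = "subband_set")
}

#' Inverse wavelet packet transform
#'
#' Reconstructs the analysis signal from a full set of terminal packet blocks;
#' exact to machine precision for the orthonormal Daubechies filters.
#'
#' @param subbands A `subband_set` from [wpd_decompose()].
#' @return Numeric vector of length `source_length`.
#' @export
wpd_reconstruct <- function(subbands) {
  stopifnot(inherits(subbands, "subband_set"))
  blocks <- subbands$blocks
  if (length(blocks) == 1L) return(blocks[[1L]][seq_len(subbands$source_length)])
  f <- daubechies_filter(subbands$wavelet$order)
  while (length(blocks) > 1L) {
    nxt <- vector("list", length(blocks) %/% 2L)
    for (b in seq_along(nxt)) {
      nxt[[b]] <- idwt_step(blocks[[2L * b - 1L]], blocks[[2L * b]], f$lo, f$hi)
    }
    blocks <- nxt
  }
  blocks[[1L]][seq_len(subbands$source_length)]
}

#' @export
print.subband_set <- function(x, ...) {
  cat(sprintf("<subband_set> %d blocks (%s order), %s%d, source length %d\n",
              length(x$blocks), x$ordering, x$wavelet$family, x$wavelet$order,
              x$source_length))
  invisible(x)
}
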