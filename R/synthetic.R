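# Synthetic two-class motor-imagery EEG.
#
# Each trial is a sustained mu + beta oscillation, shared across channels with
# fixed spatial gains, plus independent 1/f^alpha background noise per
# channel.  Event-related desynchronization (ERD) is modelled as a
# multiplicative amplitude attenuation of the rhythm on one lateral channel:
# class 1 attenuates the first lateral channel (C3), class 2 the last (C4).
# Per-subject lognormal gains on rhythm and noise amplitude make subjects
# differ, so per-subject and pooled evaluation are distinct problems.

#' Configuration of the synthetic MI-EEG generator
#'
#' @param n_subjects Number of simulated subjects.
#' @param trials_per_class_per_subject Trials per class per subject.
#' @param rate Sampling rate in Hz.
#' @param duration Trial length in seconds; `duration * rate` must be an
#'   integer >= 32.
#' @param channels Ordered channel names; first and last are the lateral
#'   channels carrying class-specific attenuation.
#' @param mu_band,beta_band Frequency bands (Hz) of the two sensorimotor
#'   rhythms.
#' @param erd_factor Amplitude attenuation of the rhythm on the affected
#'   channel, in (0, 1]; band power scales with its square. 1 = no effect.
#' @param noise_exponent Spectral slope alpha of the 1/f^alpha background.
#' @param snr_db Rhythm-to-noise power ratio in dB on an unattenuated channel.
#' @param seed Integer seed; identical configuration => identical dataset.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(n_subjects = 5L,
                              trials_per_class_per_subject = 140L,
                              rate = 100, duration = 3.5,
                              channels = c("C3", "Cz", "C4"),
                              mu_band = c(8, 12), beta_band = c(18, 26),
                              erd_factor = 0.5, noise_exponent = 1,
                              snr_db = 5, seed = NULL) {
  chk <- function(ok, field, why) {
    if (!ok) stop("invalid simulation config field '", field, "': ", why)
  }
  chk(is.numeric(n_subjects) && n_subjects >= 1 &&
        n_subjects == round(n_subjects), "n_subjects", "must be a positive integer")
  chk(is.numeric(trials_per_class_per_subject) &&
        trials_per_class_per_subject >= 1 &&
        trials_per_class_per_subject == round(trials_per_class_per_subject),
      "trials_per_class_per_subject", "must be a positive integer")
  chk(is.numeric(rate) && rate > 0, "rate", "must be positive")
  n <- rate * duration
  chk(abs(n - round(n)) < 1e-9 && n >= 32,
      "duration", "duration * rate must be an integer >= 32")
  chk(length(channels) >= 1, "channels", "need at least one channel")
  chk(length(mu_band) == 2 && mu_band[1] < mu_band[2] &&
        mu_band[2] <= rate / 2, "mu_band", "must be an increasing Hz pair below Nyquist")
  chk(length(beta_band) == 2 && beta_band[1] < beta_band[2] &&
        beta_band[2] <= rate / 2, "beta_band", "must be an increasing Hz pair below Nyquist")
  chk(is.numeric(erd_factor) && erd_factor > 0 && erd_factor <= 1,
      "erd_factor", "must lie in (0, 1]")
  chk(is.numeric(noise_exponent) && noise_exponent >= 0,
      "noise_exponent", "must be >= 0")
  chk(is.numeric(snr_db) && is.finite(snr_db), "snr_db", "must be finite")
  chk(!is.null(seed) && is.numeric(seed) && seed == round(seed),
      "seed", "an explicit integer seed is required for reproducibility")
  structure(list(n_subjects = as.integer(n_subjects),
                 trials_per_class_per_subject = as.integer(trials_per_class_per_subject),
                 rate = rate, duration = duration,
                 channels = as.character(channels),
                 mu_band = as.numeric(mu_band), beta_band = as.numeric(beta_band),
                 erd_factor = erd_factor, noise_exponent = noise_exponent,
                 snr_db = snr_db, seed = as.integer(seed)),
            class = "simulation_config")
}

#' Read a simulation configuration from JSON
#' @param path JSON file holding `simulation_config` fields.
#' @return A [simulation_config()].
#' @export
read_simulation_config <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(simulation_config, js)
}

# colored noise by spectral shaping of white Gaussian noise: amplitude
# spectrum multiplied by f^(-alpha/2), DC bin left at zero; unit variance.
colored_noise <- function(n, alpha, rate) {
  w <- stats::rnorm(n)
  if (alpha == 0) return(w)
  f <- stats::fft(w)
  freq <- seq_len(n) - 1L
  freq <- pmin(freq, n - freq) * rate / n  # two-sided frequency axis
  shape <- c(0, freq[-1L]^(-alpha / 2))
  x <- Re(stats::fft(f * shape, inverse = TRUE)) / n
  x / stats::sd(x)
}

sim_one_trial <- function(config, cls, rhythm_gain, noise_gain) {
  n <- as.integer(round(config$rate * config$duration))
  t <- seq_len(n) / config$rate
  nch <- length(config$channels)
  f_mu <- stats::runif(1, config$mu_band[1], config$mu_band[2])
  f_beta <- stats::runif(1, config$beta_band[1], config$beta_band[2])
  ph <- stats::runif(2, 0, 2 * pi)
  rhythm <- sin(2 * pi * f_mu * t + ph[1]) + 0.8 * sin(2 * pi * f_beta * t + ph[2])
  p_rhythm <- mean(rhythm^2)
  sigma <- sqrt(p_rhythm / 10^(config$snr_db / 10))
  # spatial gains: rhythm strongest laterally, slightly weaker at the vertex
  gains <- rep(1, nch)
  if (nch >= 3) gains[2:(nch - 1)] <- 0.8
  att <- rep(1, nch)
  if (nch == 1L) {
    if (cls == 1L) att[1L] <- config$erd_factor
  } else if (cls == 1L) {
    att[1L] <- config$erd_factor
  } else {
    att[nch] <- config$erd_factor
  }
  m <- matrix(0, nrow = nch, ncol = n)
  for (ch in seq_len(nch)) {
    noise <- colored_noise(n, config$noise_exponent, config$rate) * sigma
    m[ch, ] <- rhythm_gain * gains[ch] * att[ch] * rhythm + noise_gain * noise
  }
  m
}

sim_generate <- function(config, null_labels) {
  tpc <- config$trials_per_class_per_subject
  segs <- vector("list", config$n_subjects * 2L * tpc)
  k <- 1L
  for (s in seq_len(config$n_subjects)) {
    subj <- sprintf("S%02d", s)
    rhythm_gain <- exp(stats::rnorm(1, 0, 0.25))
    noise_gain <- exp(stats::rnorm(1, 0, 0.25))
    labels <- rep(c(1L, 2L), each = tpc)
    if (null_labels) labels <- sample(labels)
    for (lab in labels) {
      gen_cls <- if (null_labels) 0L else lab  # null: no class-linked signal
      m <- sim_one_trial(config, gen_cls, rhythm_gain, noise_gain)
      segs[[k]] <- eeg_segment(m, rate = config$rate, label = lab,
                               subject = subj,
                               channel_names = config$channels)
      k <- k + 1L
    }
  }
  meta <- c(unclass(config),
            list(generator = "mieeg-synthetic", null = null_labels))
  meta$channels <- paste(config$channels, collapse = ",")
  meta$mu_band <- paste(config$mu_band, collapse = "-")
  meta$beta_band <- paste(config$beta_band, collapse = "-")
  eeg_dataset(segs, metadata = meta)
}

#' Generate a synthetic two-class MI-EEG dataset
#'
#' Produces `n_subjects * 2 * trials_per_class_per_subject` labelled trials.
#' Class 1 attenuates the sustained mu/beta rhythm on the first channel by
#' `erd_factor` (amplitude), class 2 on the last channel; the rhythm is summed
#' with independent `1/f^alpha` noise at `snr_db`.
#'
#' @param config A [simulation_config()].
#' @return An [eeg_dataset()].
#' @examples
#' ds <- generate_dataset(simulation_config(n_subjects = 1,
#'   trials_per_class_per_subject = 2, seed = 1))
#' length(ds)  # 4
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  withr::with_seed(config$seed, sim_generate(config, null_labels = FALSE))
}

#' Generate a label-independent null dataset
#'
#' Same signal model with `erd_factor` forced to 1 (no class-linked structure)
#' and balanced labels assigned by random permutation, independent of signal
#' content.  Any classifier's cross-validated accuracy on this dataset should
#' be statistically indistinguishable from 50%.
#'
#' @param config A [simulation_config()]; its `erd_factor` is ignored.
#' @return An [eeg_dataset()].
#' @export
generate_null_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  config$erd_factor <- 1
  withr::with_seed(config$seed, sim_generate(config, null_labels = TRUE))
}
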