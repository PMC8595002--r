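# Minimal European Data Format (EDF) support: one data record per trial,
# class labels carried in an extra 1-sample-per-record "TRIAL_LABEL" signal
# (plain EDF has no per-record annotation slot), subject codes and the exact
# sampling rate in a JSON sidecar next to the file.  Samples are quantized to
# the format's 16-bit integers, so a round trip is exact only to
# (phys_max - phys_min) / 65535 per channel.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1L, width)
  formatC(x, width = width, flag = "-")
}

write_edf_segments <- function(dataset, path) {
  segs <- dataset$segments
  nsamp <- ncol(segs[[1L]]$samples)
  if (!all(vapply(segs, function(s) ncol(s$samples), integer(1)) == nsamp)) {
    stop("EDF output requires equal-length trials")
  }
  nch <- nrow(segs[[1L]]$samples)
  rate <- segs[[1L]]$rate
  ntrial <- length(segs)
  ns <- nch + 1L  # + label signal
  # per-channel physical range over the whole dataset
  pmin <- rep(Inf, nch); pmax <- rep(-Inf, nch)
  for (s in segs) {
    pmin <- pmin(pmin, apply(s$samples, 1L, min))
    pmax <- pmax(pmax, apply(s$samples, 1L, max))
  }
  flat <- pmax - pmin < 1e-12
  pmin[flat] <- pmin[flat] - 1
  pmax[flat] <- pmax[flat] + 1
  dmin <- -32768; dmax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  hdr_bytes <- 256L + 256L * ns
  hdr <- paste0(
    edf_pad("0", 8), edf_pad("X X X X", 80),
    edf_pad("Startdate 01-JAN-2000 mieeg", 80),
    "01.01.00", "00.00.00",
    edf_pad(hdr_bytes, 8), edf_pad("", 44),
    edf_pad(ntrial, 8), edf_pad(format(nsamp / rate, digits = 7), 8),
    edf_pad(ns, 4))
  writeChar(hdr, con, eos = NULL)
  labels16 <- c(vapply(segs[[1L]]$channel_names, edf_pad, "", width = 16),
                edf_pad("TRIAL_LABEL", 16))
  fields <- list(
    labels16,
    rep(edf_pad("", 80), ns),                                   # transducer
    c(rep(edf_pad("uV", 8), nch), edf_pad("", 8)),              # phys dim
    c(vapply(pmin, edf_pad, "", width = 8), edf_pad(0, 8)),     # phys min
    c(vapply(pmax, edf_pad, "", width = 8), edf_pad(3, 8)),     # phys max
    rep(edf_pad(dmin, 8), ns),                                  # dig min
    rep(edf_pad(dmax, 8), ns),                                  # dig max
    rep(edf_pad("", 80), ns),                                   # prefiltering
    c(rep(edf_pad(nsamp, 8), nch), edf_pad(1, 8)),              # samples/rec
    rep(edf_pad("", 32), ns))
  for (f in fields) writeChar(paste0(f, collapse = ""), con, eos = NULL)

  scl <- (dmax - dmin) / (pmax - pmin)
  lab_scl <- (dmax - dmin) / 3  # label signal physical range [0, 3]
  for (s in segs) {
    for (ch in seq_len(nch)) {
      dig <- round((s$samples[ch, ] - pmin[ch]) * scl[ch] + dmin)
      writeBin(as.integer(pmin(pmax(dig, dmin), dmax)), con, size = 2L,
               endian = "little")
    }
    writeBin(as.integer(round(s$label * lab_scl + dmin)), con, size = 2L,
             endian = "little")
  }
  side <- list(format = "mieeg-edf", version = 1L, rate = rate,
               subjects = vapply(segs, function(s) s$subject, character(1)),
               metadata = dataset$metadata)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

read_edf_segments <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  rd(8)   # version
  rd(80); rd(80); rd(8); rd(8)  # patient, recording, date, time
  rd(8)   # header bytes
  rd(44)  # reserved
  ntrial <- as.integer(rd(8))
  duration <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ntrial) || is.na(ns) || ns < 2L) stop("unreadable EDF header: ", path)
  sig_labels <- trimws(vapply(seq_len(ns), function(i) rd(16), ""))
  for (i in seq_len(ns)) rd(80)             # transducer
  for (i in seq_len(ns)) rd(8)              # phys dim
  pmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(80)             # prefiltering
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(32)             # reserved

  lab_idx <- which(sig_labels == "TRIAL_LABEL")
  if (length(lab_idx) != 1L) {
    stop("EDF file lacks the TRIAL_LABEL signal; not a trial dump: ", path)
  }
  ch_idx <- setdiff(seq_len(ns), lab_idx)
  nsamp <- spr[ch_idx[1L]]
  rate <- nsamp / duration
  subjects <- rep("S1", ntrial)
  meta <- list()
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    sj <- jsonlite::read_json(side, simplifyVector = TRUE)
    if (!is.null(sj$rate)) rate <- sj$rate
    if (!is.null(sj$subjects)) subjects <- sj$subjects
    if (!is.null(sj$metadata)) meta <- as.list(sj$metadata)
  }
  scl <- (pmax - pmin) / (dmax - dmin)
  segs <- vector("list", ntrial)
  for (t in seq_len(ntrial)) {
    m <- matrix(0, nrow = length(ch_idx), ncol = nsamp)
    lab <- NA_integer_
    row <- 1L
    for (i in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[i], size = 2L, signed = TRUE,
                     endian = "little")
      phys <- (dig - dmin[i]) * scl[i] + pmin[i]
      if (i == lab_idx) {
        lab <- as.integer(round(phys[1L]))
      } else {
        m[row, ] <- phys
        row <- row + 1L
      }
    }
    if (!lab %in% c(1L, 2L)) {
      stop("trial ", t, " carries label ", lab, "; labels must be in {1, 2}")
    }
    segs[[t]] <- eeg_segment(m, rate = rate, label = lab,
                             subject = subjects[t],
                             channel_names = sig_labels[ch_idx])
  }
  eeg_dataset(segs, metadata = meta)
}
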