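# Minimal EDF (European Data Format) reader/writer.
#
# Implements the plain 16-bit EDF container: a 256-byte fixed header,
# 256 bytes of header per signal, then data records of little-endian 16-bit
# two's-complement samples with linear physical/digital scaling. Enough for
# round-tripping equal-rate multichannel EEG; EDF+ annotations, discontinuous
# records and per-signal rates beyond what we write are not supported.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width, flag = " ")
}

#' Write a recording as 16-bit EDF
#'
#' One data record per second. Physical scaling spans the observed per-channel
#' range, so the quantization step is \code{(max - min) / (2^16 - 1)} per
#' channel.
#'
#' @param recording an [eeg_recording()].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_edf <- function(recording, path) {
  stopifnot(inherits(recording, "eeg_recording"))
  fs <- recording$sampling_rate_hz
  if (abs(fs - round(fs)) > 1e-9) stop("EDF writer requires integer sampling rate")
  fs <- as.integer(round(fs))
  x <- recording$data
  ns <- nrow(x)
  # pad to a whole number of 1 s records
  n_rec <- ceiling(ncol(x) / fs)
  if (ncol(x) < n_rec * fs) {
    pad <- matrix(0, ns, n_rec * fs - ncol(x))
    x <- cbind(x, pad)
  }
  pmin_ <- apply(x, 1, min)
  pmax_ <- apply(x, 1, max)
  flat <- pmax_ - pmin_ <= 0
  pmax_[flat] <- pmin_[flat] + 1
  dmin <- -32768L; dmax <- 32767L
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8),
    edf_pad(recording$subject_id, 80),
    edf_pad("plvnet", 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256 * (1 + ns), 8),
    edf_pad("", 44),
    edf_pad(n_rec, 8),
    edf_pad(1, 8),           # record duration, seconds
    edf_pad(ns, 4)
  )
  writeChar(hdr, con, eos = NULL)
  fld <- function(vals, width) writeChar(paste0(vapply(vals, edf_pad, "", width = width),
                                                collapse = ""), con, eos = NULL)
  fld(recording$channel_labels, 16)
  fld(rep("", ns), 80)                       # transducer
  fld(rep("uV", ns), 8)                      # physical dimension
  fld(sprintf("%.8g", pmin_), 8)
  fld(sprintf("%.8g", pmax_), 8)
  fld(rep(dmin, ns), 8)
  fld(rep(dmax, ns), 8)
  fld(rep("", ns), 80)                       # prefiltering
  fld(rep(fs, ns), 8)                        # samples per record
  fld(rep("", ns), 32)                       # reserved
  scale <- (pmax_ - pmin_) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    dig <- round((x[, idx, drop = FALSE] - pmin_) / scale) + dmin
    dig[dig < dmin] <- dmin; dig[dig > dmax] <- dmax
    writeBin(as.integer(t(dig)), con, size = 2L, endian = "little")
  }
  invisible(path)
}

#' Read a 16-bit EDF file
#'
#' @param path EDF file path.
#' @return an [eeg_recording()] (sampling rate and labels from the header).
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8)                                   # version
  subject <- rd(80)
  rd(80); rd(8); rd(8)
  header_bytes <- as.integer(rd(8))
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1L) stop("malformed EDF header")
  rdv <- function(width) vapply(seq_len(ns), function(i) rd(width), "")
  labels <- rdv(16)
  rdv(80); rdv(8)
  pmin_ <- as.numeric(rdv(8)); pmax_ <- as.numeric(rdv(8))
  dmin <- as.numeric(rdv(8)); dmax <- as.numeric(rdv(8))
  rdv(80)
  spr <- as.integer(rdv(8))
  rdv(32)
  if (length(unique(spr)) != 1L)
    stop("EDF reader supports equal per-signal sampling rates only")
  seek(con, header_bytes)
  x <- matrix(0, ns, n_rec * spr[1])
  scale <- (pmax_ - pmin_) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    raw <- readBin(con, "integer", n = ns * spr[1], size = 2L,
                   signed = TRUE, endian = "little")
    if (length(raw) < ns * spr[1]) stop("truncated EDF data record")
    block <- matrix(raw, nrow = spr[1], ncol = ns)
    x[, ((r - 1L) * spr[1] + 1L):(r * spr[1])] <- t((block - rep(dmin, each = spr[1])) *
      rep(scale, each = spr[1]) + rep(pmin_, each = spr[1]))
  }
  eeg_recording(x, spr[1] / rec_dur, labels, subject_id = subject)
}
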