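#' EEG frequency band definitions
#'
#' The four classical sub-bands used for the band-wise network analysis.
#' \code{center_hz} is the geometric center-of-band carrier used by the
#' synthetic generator.
#'
#' @param names which bands to return (subset of delta/theta/alpha/beta).
#' @return named list of \code{band_definition} objects.
#' @export
eeg_bands <- function(names = c("delta", "theta", "alpha", "beta")) {
  all <- list(
    delta = band_definition("delta", 0.5, 4, 2.25),
    theta = band_definition("theta", 4, 7, 5.5),
    alpha = band_definition("alpha", 8, 12, 10),
    beta  = band_definition("beta", 13, 30, 21.5)
  )
  names <- match.arg(names, choices = names(all), several.ok = TRUE)
  all[names]
}

#' Create a band definition
#'
#' @param name band name.
#' @param low_hz,high_hz band edges in Hz, 0 < low < high.
#' @param center_hz nominal band center in Hz (defaults to the midpoint).
#' @return list of class \code{band_definition}.
#' @export
band_definition <- function(name, low_hz, high_hz, center_hz = (low_hz + high_hz) / 2) {
  if (!is.character(name) || length(name) != 1L) stop("band name must be a string")
  if (!(low_hz > 0 && high_hz > low_hz)) stop("band edges must satisfy 0 < low < high")
  structure(list(name = name, low_hz = low_hz, high_hz = high_hz,
                 center_hz = center_hz),
            class = "band_definition")
}

#' Construct an EEG recording object
#'
#' The basic signal container: a channels x samples numeric matrix in
#' microvolts with a sampling rate and ordered channel labels.
#'
#' @param data channels x samples numeric matrix.
#' @param sampling_rate_hz sampling rate in Hz.
#' @param channel_labels character vector, one label per row of \code{data}.
#' @param subject_id subject identifier string.
#' @return list of class \code{eeg_recording}.
#' @export
eeg_recording <- function(data, sampling_rate_hz, channel_labels,
                          subject_id = "subject") {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("data must be numeric")
  if (anyNA(data) || any(!is.finite(data))) stop("data contains NaN/Inf")
  if (nrow(data) != length(channel_labels))
    stop("channel count (", nrow(data), ") != label count (",
         length(channel_labels), ")")
  if (!(is.numeric(sampling_rate_hz) && sampling_rate_hz > 0))
    stop("sampling_rate_hz must be positive")
  structure(list(data = data, sampling_rate_hz = sampling_rate_hz,
                 channel_labels = as.character(channel_labels),
                 subject_id = subject_id),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s: %d channels x %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, nrow(x$data), ncol(x$data), x$sampling_rate_hz,
              ncol(x$data) / x$sampling_rate_hz))
  invisible(x)
}

# Squared-magnitude response of an order-`order` digital Butterworth band-pass
# at normalized frequencies f (Hz), via bilinear pre-warping. One forward pass.
butter_bandpass_gain <- function(f, low_hz, high_hz, fs, order = 4) {
  w <- tan(pi * pmin(f, fs / 2 - 1e-9) / fs)
  w1 <- tan(pi * low_hz / fs)
  w2 <- tan(pi * high_hz / fs)
  b <- w2 - w1
  w0sq <- w1 * w2
  q <- ifelse(w > 0, (w^2 - w0sq) / (b * w), Inf)
  sqrt(1 / (1 + q^(2 * order)))
}

#' Zero-phase band-pass filter
#'
#' Applies a zero-phase band-pass to every channel of a recording. The filter
#' is the squared magnitude of an order-4 Butterworth band-pass (the
#' forward-backward response), applied in the frequency domain so that the
#' phase response is exactly zero; a causal filter would add a
#' frequency-dependent phase lag, which is unacceptable upstream of a
#' phase-synchronization estimator. Filtering is applied to the full
#' continuous record (before epoching). The FFT implementation is circular,
#' so callers should discard a guard interval at the record ends (the
#' pipeline drops 1 s at each end before segmentation).
#'
#' @param recording an [eeg_recording()].
#' @param band a \code{band_definition}.
#' @param order Butterworth order per pass (default 4).
#' @return filtered \code{eeg_recording} of identical shape.
#' @export
bandpass <- function(recording, band, order = 4) {
  stopifnot(inherits(recording, "eeg_recording"),
            inherits(band, "band_definition"))
  fs <- recording$sampling_rate_hz
  if (band$high_hz >= fs / 2)
    stop("band [", band$low_hz, ",", band$high_hz,
         "] Hz exceeds Nyquist (", fs / 2, " Hz)")
  n <- ncol(recording$data)
  freqs <- (seq_len(n) - 1) / n * fs
  freqs <- pmin(freqs, fs - freqs)  # two-sided spectrum folding
  gain <- butter_bandpass_gain(freqs, band$low_hz, band$high_hz, fs, order)^2
  x <- t(recording$data)
  xf <- Re(stats::mvfft(stats::mvfft(x) * gain, inverse = TRUE)) / n
  out <- recording
  out$data <- t(xf)
  out$band <- band
  out
}

#' Segment a recording into non-overlapping epochs
#'
#' Splits a continuous recording into \code{n_epochs} non-overlapping epochs
#' of \code{epoch_length_s} seconds. Following the source protocol the
#' placement is random: epoch start offsets are drawn uniformly at random
#' subject to non-overlap (deterministic given \code{seed}), and epochs are
#' returned sorted by start time. \code{contiguous = TRUE} gives
#' deterministic back-to-back epochs starting at the first sample.
#'
#' @param recording an [eeg_recording()].
#' @param epoch_length_s epoch length in seconds (default 15).
#' @param n_epochs number of epochs (default 8).
#' @param seed integer seed for the random placement.
#' @param contiguous logical; back-to-back placement instead of random.
#' @return list of class \code{epoch_set} with fields \code{epochs} (list of
#'   channels x samples matrices), \code{starts} (1-based start samples),
#'   \code{epoch_length_s}, \code{sampling_rate_hz}, \code{channel_labels},
#'   \code{subject_id}, and \code{band} if the recording carries one.
#' @export
segment_epochs <- function(recording, epoch_length_s = 15, n_epochs = 8,
                           seed = 1L, contiguous = FALSE) {
  stopifnot(inherits(recording, "eeg_recording"))
  fs <- recording$sampling_rate_hz
  len <- round(epoch_length_s * fs)
  total <- ncol(recording$data)
  if (n_epochs < 1L || len < 1L) stop("invalid epoch request")
  if (n_epochs * len > total)
    stop("recording too short: need ", n_epochs * len, " samples for ",
         n_epochs, " x ", epoch_length_s, " s, have ", total)
  if (contiguous) {
    starts <- (seq_len(n_epochs) - 1L) * len + 1L
  } else {
    # place epochs by distributing the slack uniformly between them
    slack <- total - n_epochs * len
    set.seed(as.integer(seed))
    gaps <- if (slack > 0) {
      cuts <- sort(sample.int(slack + n_epochs, n_epochs))
      diff(c(0L, cuts)) - 1L
    } else rep(0L, n_epochs)
    starts <- cumsum(gaps) + (seq_len(n_epochs) - 1L) * len + 1L
  }
  epochs <- lapply(starts, function(s) recording$data[, s:(s + len - 1L), drop = FALSE])
  structure(list(epochs = epochs, starts = starts,
                 epoch_length_s = epoch_length_s,
                 sampling_rate_hz = fs,
                 channel_labels = recording$channel_labels,
                 subject_id = recording$subject_id,
                 band = recording$band),
            class = "epoch_set")
}

#' Read a multichannel recording
#'
#' Reads either a minimal 16-bit EDF file or a delimited numeric matrix
#' (channels in columns, optional header row of channel labels). Labels are
#' normalized to canonical 10-20 spelling by case-insensitive match; unknown
#' labels trigger a warning and are kept with lobe "unassigned". A channel
#' count different from the 30-channel montage triggers a warning and
#' processing continues with the observed N.
#'
#' @param path file path.
#' @param format \code{"edf"}, \code{"tsv"} or \code{"csv"}; guessed from the
#'   file extension by default.
#' @param sampling_rate_hz required for delimited matrices (EDF stores it).
#' @param expected_channels montage size checked with a warning (default 30).
#' @return an [eeg_recording()].
#' @export
read_recording <- function(path, format = c("auto", "edf", "tsv", "csv"),
                           sampling_rate_hz = 250,
                           expected_channels = 30L) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, edf = "edf", csv = "csv", "tsv")
  }
  rec <- if (format == "edf") {
    read_edf(path)
  } else {
    sep <- if (format == "csv") "," else "\t"
    first <- readLines(path, n = 1L)
    fields <- strsplit(first, sep, fixed = TRUE)[[1]]
    has_header <- anyNA(suppressWarnings(as.numeric(fields)))
    tab <- utils::read.table(path, sep = sep, header = has_header,
                             check.names = FALSE)
    labels <- if (has_header) colnames(tab) else paste0("ch", seq_len(ncol(tab)))
    eeg_recording(t(as.matrix(tab)), sampling_rate_hz, labels,
                  subject_id = tools::file_path_sans_ext(basename(path)))
  }
  rec$channel_labels <- normalize_labels(rec$channel_labels)
  if (!is.null(expected_channels) && nrow(rec$data) != expected_channels)
    warning("recording has ", nrow(rec$data), " channels, montage expects ",
            expected_channels, "; continuing with N = ", nrow(rec$data))
  rec
}

#' Write a recording to disk
#'
#' @param recording an [eeg_recording()].
#' @param path output path.
#' @param format \code{"edf"}, \code{"tsv"} or \code{"csv"}; guessed from the
#'   extension by default. Delimited output has one column per channel with a
#'   label header row.
#' @return \code{path}, invisibly.
#' @export
write_recording <- function(recording, path, format = c("auto", "edf", "tsv", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, edf = "edf", csv = "csv", "tsv")
  }
  if (format == "edf") {
    write_edf(recording, path)
  } else {
    sep <- if (format == "csv") "," else "\t"
    tab <- as.data.frame(t(recording$data))
    colnames(tab) <- recording$channel_labels
    utils::write.table(tab, path, sep = sep, row.names = FALSE,
                       quote = FALSE)
  }
  invisible(path)
}
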