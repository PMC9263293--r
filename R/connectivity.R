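# Phase extraction and phase-locking-value estimation.

# FFT analytic signal (one-sided spectrum doubling)
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) {
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Instantaneous phase of a band-limited signal
#'
#' Phase of the analytic signal (FFT-based Hilbert transform). Valid for
#' band-limited input; edge samples carry transform edge effects, which is why
#' downstream PLV trims a fraction of each epoch edge.
#'
#' @param signal real numeric vector, length >= 2.
#' @return numeric vector of phases in (-pi, pi].
#' @export
instantaneous_phase <- function(signal) {
  if (length(signal) < 2L) stop("signal must have length >= 2")
  if (anyNA(signal) || any(!is.finite(signal))) stop("signal contains NaN/Inf")
  if (stats::var(signal) == 0)
    stop("constant signal: instantaneous phase undefined")
  Arg(analytic_signal(signal))
}

#' Unwrap a phase series
#'
#' Removes 2*pi jumps so the cumulative phase is continuous.
#'
#' @param phase numeric vector of wrapped phases (radians).
#' @return unwrapped phase vector.
#' @export
unwrap_phase <- function(phase) {
  d <- diff(phase)
  d <- d - 2 * pi * round(d / (2 * pi))
  cumsum(c(phase[1], d))
}

#' Phase-locking value of two phase series
#'
#' Modulus of the time-averaged unit phasor of the relative phase:
#' \code{PLV = sqrt(mean(cos(d))^2 + mean(sin(d))^2)} with
#' \code{d = phase_a - phase_b}. Equals 1 for perfect locking, 0 for no
#' consistent phase relation. Symmetric in its arguments and invariant under
#' adding a common constant to both series.
#'
#' @param phase_a,phase_b numeric phase vectors of equal length (radians).
#' @return PLV in [0, 1].
#' @export
plv <- function(phase_a, phase_b) {
  if (length(phase_a) != length(phase_b))
    stop("phase series lengths differ (", length(phase_a), " vs ",
         length(phase_b), ")")
  if (length(phase_a) < 1L) stop("empty phase series")
  d <- phase_a - phase_b
  sqrt(mean(cos(d))^2 + mean(sin(d))^2)
}

# phases for all channels of one epoch, with edge trim; returns T' x N matrix
epoch_phases <- function(epoch, trim = 0.05) {
  n <- ncol(epoch)
  keep <- if (trim > 0) {
    tr <- round(trim * n)
    (tr + 1L):(n - tr)
  } else seq_len(n)
  N <- nrow(epoch)
  x <- t(epoch)                        # samples x channels
  mu <- colMeans(x)
  dead <- colSums((x - rep(mu, each = n))^2) == 0
  # one-sided spectrum doubling applied to all channels at once
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) { h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2 }
  else h[2:((n + 1) / 2)] <- 2
  z <- stats::mvfft(stats::mvfft(x) * h, inverse = TRUE)
  ph <- Arg(z[keep, , drop = FALSE])
  ph[, dead] <- NA_real_
  list(phases = ph, dead = dead)
}

#' PLV matrix of an epoch set
#'
#' Computes the N x N phase-locking-value matrix of a subject in one band.
#' Default aggregation (\code{"epoch_mean"}) computes the PLV within each
#' epoch and averages the per-epoch values, bounding non-stationarity at the
#' epoch scale; \code{"pooled"} averages the relative-phase phasors over all
#' retained samples of all epochs before taking the modulus, which removes
#' the per-epoch small-sample (Rayleigh) floor and is the right choice for
#' convergence checks against ground truth. A fraction \code{trim} of samples
#' at each epoch edge is dropped before estimation to suppress Hilbert edge
#' effects. Zero-variance channels yield masked (NA) rows/columns, flagged in
#' the \code{mask} attribute.
#'
#' @param epoch_set an [segment_epochs()] result (list of channels x samples
#'   epochs), or a single channels x samples matrix treated as one epoch.
#' @param trim fraction of samples trimmed from each epoch edge (default
#'   0.05).
#' @param aggregate \code{"epoch_mean"} (default) or \code{"pooled"}.
#' @return object of class \code{plv_matrix}: list with \code{values}
#'   (symmetric N x N, unit diagonal, NA where masked), \code{mask} (logical
#'   N x N, TRUE = undefined), \code{channel_labels}, \code{band},
#'   \code{subject_id}, \code{n_epochs_used}.
#' @export
plv_matrix <- function(epoch_set, trim = 0.05,
                       aggregate = c("epoch_mean", "pooled")) {
  aggregate <- match.arg(aggregate)
  if (is.matrix(epoch_set))
    epoch_set <- list(epochs = list(epoch_set),
                      channel_labels = rownames(epoch_set),
                      subject_id = "subject", band = NULL)
  epochs <- epoch_set$epochs
  if (length(epochs) < 1L) stop("need at least one epoch")
  N <- nrow(epochs[[1]])
  labels <- epoch_set$channel_labels
  if (is.null(labels)) labels <- paste0("ch", seq_len(N))
  acc <- matrix(0, N, N)        # epoch_mean: sum of per-epoch PLV
  acc_re <- matrix(0, N, N)     # pooled: accumulated phasor sums
  acc_im <- matrix(0, N, N)
  tot <- 0
  dead_any <- logical(N)
  for (ep in epochs) {
    p <- epoch_phases(ep, trim)
    dead_any <- dead_any | p$dead
    ph <- p$phases
    ph[, p$dead] <- 0  # placeholder; masked later
    Tn <- nrow(ph)
    Cm <- cos(ph); Sm <- sin(ph)
    # sum over t of cos/sin of (phi_i - phi_j), via real cross-products
    sc <- crossprod(Cm) + crossprod(Sm)       # sum cos(di - dj)
    ss <- crossprod(Sm, Cm) - crossprod(Cm, Sm)  # sum sin(di - dj)
    if (aggregate == "epoch_mean") {
      acc <- acc + sqrt((sc / Tn)^2 + (ss / Tn)^2)
    } else {
      acc_re <- acc_re + sc
      acc_im <- acc_im + ss
      tot <- tot + Tn
    }
  }
  vals <- if (aggregate == "epoch_mean") acc / length(epochs)
          else sqrt((acc_re / tot)^2 + (acc_im / tot)^2)
  vals <- (vals + t(vals)) / 2
  diag(vals) <- 1
  mask <- matrix(FALSE, N, N)
  if (any(dead_any)) {
    mask[dead_any, ] <- TRUE
    mask[, dead_any] <- TRUE
    diag(mask) <- FALSE
    vals[mask] <- NA_real_
  }
  dimnames(vals) <- list(labels, labels)
  dimnames(mask) <- list(labels, labels)
  structure(list(values = vals, mask = mask, channel_labels = labels,
                 band = epoch_set$band, subject_id = epoch_set$subject_id,
                 n_epochs_used = length(epochs), aggregate = aggregate),
            class = "plv_matrix")
}

#' @export
print.plv_matrix <- function(x, ...) {
  cat(sprintf("<plv_matrix> %s%s: %d x %d, %d epoch(s), %s aggregation%s\n",
              x$subject_id,
              if (!is.null(x$band)) paste0(" [", x$band$name, "]") else "",
              nrow(x$values), ncol(x$values), x$n_epochs_used, x$aggregate,
              if (any(x$mask)) sprintf(", %d masked entries", sum(x$mask)) else ""))
  invisible(x)
}

#' Serialize / read a PLV matrix
#'
#' Writes the matrix as labelled TSV plus a JSON sidecar
#' (\code{<path>.json}) carrying subject, band, epoch count, aggregation and
#' the mask.
#'
#' @param pm a [plv_matrix()].
#' @param path TSV output path.
#' @return \code{path}, invisibly.
#' @export
write_plv_matrix <- function(pm, path) {
  tab <- as.data.frame(pm$values)
  utils::write.table(cbind(channel = pm$channel_labels, tab), path,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  side <- list(subject_id = pm$subject_id,
               band = if (!is.null(pm$band)) pm$band[c("name", "low_hz", "high_hz")] else NULL,
               n_epochs_used = pm$n_epochs_used,
               aggregate = pm$aggregate,
               masked = which(pm$mask, arr.ind = TRUE))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_plv_matrix
#' @param path TSV path written by [write_plv_matrix()].
#' @export
read_plv_matrix <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE)
  labels <- tab$channel
  vals <- as.matrix(tab[, -1, drop = FALSE])
  dimnames(vals) <- list(labels, labels)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  band <- if (!is.null(side$band))
    band_definition(side$band$name, side$band$low_hz, side$band$high_hz) else NULL
  mask <- matrix(FALSE, nrow(vals), ncol(vals))
  if (length(side$masked)) mask[as.matrix(side$masked)] <- TRUE
  structure(list(values = vals, mask = mask, channel_labels = labels,
                 band = band, subject_id = side$subject_id,
                 n_epochs_used = side$n_epochs_used,
                 aggregate = side$aggregate),
            class = "plv_matrix")
}
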