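# Synthetic phase-coupled EEG cohorts with analytically known connectivity.
#
# Signal model, per frequency band:
#   coupled cluster: every channel in the cluster shares a common phase
#     c(t) = 2*pi*f_c*t + slow random walk; each channel adds independent
#     von Mises(0, kappa) jitter held constant over half-carrier-period
#     blocks, so the phase process stays inside the analytic-signal
#     bandwidth and the Hilbert estimator can track it. The model-implied
#     PLV between two cluster channels with concentrations ki, kj is
#     R(ki) * R(kj) with R(k) = I1(k)/I0(k) (so R(k)^2 for a matched pair).
#   uncoupled channel: its own phase 2*pi*f_c*t + fast random walk
#     (default 0.2 rad/sample), giving a spectrally plausible oscillation
#     with no stable phase relation to anything else.
# The channel signal is amplitude * cos(phase); bands are summed and white
# measurement noise is added last.

#' Model-implied PLV of a von Mises-jittered pair
#'
#' Closed form for two channels sharing a common phase, each with independent
#' von Mises(0, kappa) jitter: \code{(I1(kappa)/I0(kappa))^2}, where I0 and I1
#' are modified Bessel functions of the first kind.
#'
#' @param kappa concentration parameter(s), >= 0.
#' @return true PLV value(s) in [0, 1].
#' @export
plv_von_mises <- function(kappa) {
  if (any(kappa < 0)) stop("kappa must be >= 0")
  r <- ifelse(kappa > 0, besselI(kappa, 1) / besselI(kappa, 0), 0)
  r^2
}

#' Draw from the von Mises distribution
#'
#' Best-Fisher rejection sampler for von Mises(0, kappa); kappa = 0 falls back
#' to the uniform circular distribution.
#'
#' @param n number of draws.
#' @param kappa concentration, >= 0.
#' @return numeric vector of angles in (-pi, pi].
#' @export
rvonmises <- function(n, kappa) {
  if (kappa < 0) stop("kappa must be >= 0")
  if (kappa < 1e-12) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    v <- sign(u3[ok] - 0.5) * acos(pmin(1, pmax(-1, f[ok])))
    k <- sum(ok)
    if (k > 0) { out[(got + 1L):(got + k)] <- v; got <- got + k }
  }
  out
}

# jitter refresh interval: half the carrier period, >= 1 sample
jitter_block <- function(sampling_rate_hz, band_center_hz) {
  max(1L, as.integer(round(sampling_rate_hz / (2 * band_center_hz))))
}

# piecewise-constant von Mises jitter series of length n
block_jitter <- function(n, kappa, block) {
  nb <- ceiling(n / block)
  rep(rvonmises(nb, kappa), each = block)[seq_len(n)]
}

#' Simulate one phase-coupled channel pair
#'
#' Two band-centered oscillations sharing a common phase (linear trend plus a
#' slow random walk), each with independent block-wise von Mises phase jitter
#' and optional additive white noise. The ground-truth PLV is the closed form
#' [plv_von_mises()].
#'
#' @param kappa von Mises concentration (>= 0); larger = tighter locking.
#' @param n_samples samples per channel (> 0).
#' @param band_center_hz carrier frequency in Hz.
#' @param sampling_rate_hz sampling rate in Hz.
#' @param seed integer seed.
#' @param noise_sd additive white Gaussian noise sd (amplitude units).
#' @param amplitude oscillation amplitude.
#' @param walk_sd per-sample sd of the shared slow phase random walk (rad).
#' @return list with \code{x}, \code{y} (numeric signal vectors),
#'   \code{true_plv}, and the generating parameters.
#' @export
simulate_channel_pair <- function(kappa, n_samples, band_center_hz = 10,
                                  sampling_rate_hz = 250, seed = 1L,
                                  noise_sd = 0, amplitude = 1,
                                  walk_sd = 0.02) {
  if (length(kappa) != 1L || is.na(kappa) || kappa < 0)
    stop("kappa must be a single value >= 0")
  if (length(n_samples) != 1L || is.na(n_samples) || n_samples <= 0)
    stop("n_samples must be positive")
  n_samples <- as.integer(n_samples)
  set.seed(as.integer(seed))
  tt <- (seq_len(n_samples) - 1) / sampling_rate_hz
  common <- 2 * pi * band_center_hz * tt + stats::runif(1, -pi, pi) +
    cumsum(stats::rnorm(n_samples, 0, walk_sd))
  blk <- jitter_block(sampling_rate_hz, band_center_hz)
  jx <- if (is.infinite(kappa)) 0 else block_jitter(n_samples, kappa, blk)
  jy <- if (is.infinite(kappa)) 0 else block_jitter(n_samples, kappa, blk)
  x <- amplitude * cos(common + jx)
  y <- amplitude * cos(common + jy)
  if (noise_sd > 0) {
    x <- x + stats::rnorm(n_samples, 0, noise_sd)
    y <- y + stats::rnorm(n_samples, 0, noise_sd)
  }
  list(x = x, y = y,
       true_plv = if (is.infinite(kappa)) 1 else plv_von_mises(kappa),
       kappa = kappa, band_center_hz = band_center_hz,
       sampling_rate_hz = sampling_rate_hz, jitter_block = blk)
}

#' Specify per-band phase coupling for the cohort generator
#'
#' Coupled pairs are grouped into connected components; all channels of a
#' component share one common phase and each carries von Mises jitter with the
#' component's concentration, so the implied true PLV within a component is
#' \code{plv_von_mises(kappa)} and 0 across components. All pairs inside one
#' component must therefore state the same kappa.
#'
#' @param band_center_hz carrier frequency (Hz).
#' @param pairs data.frame with columns \code{i}, \code{j} (1-based channel
#'   indices) and \code{kappa} (>= 0); may have zero rows.
#' @param background_noise_sd white measurement noise sd added after band
#'   synthesis.
#' @param amplitude oscillation amplitude for this band.
#' @return list of class \code{coupling_spec}.
#' @export
coupling_spec <- function(band_center_hz, pairs = NULL,
                          background_noise_sd = 0, amplitude = 1) {
  if (is.null(pairs)) pairs <- data.frame(i = integer(), j = integer(),
                                          kappa = numeric())
  stopifnot(all(c("i", "j", "kappa") %in% names(pairs)))
  if (nrow(pairs)) {
    if (any(pairs$i == pairs$j)) stop("self-coupling (i == j) is not allowed")
    if (any(pairs$kappa < 0)) stop("kappa must be >= 0")
    key <- paste(pmin(pairs$i, pairs$j), pmax(pairs$i, pairs$j))
    if (anyDuplicated(key)) stop("duplicate unordered coupling pairs")
  }
  structure(list(band_center_hz = band_center_hz, pairs = pairs,
                 background_noise_sd = background_noise_sd,
                 amplitude = amplitude),
            class = "coupling_spec")
}

# connected components of the coupling graph; checks kappa consistency.
# Returns list of list(nodes=..., kappa=...)
coupling_components <- function(pairs, n_channels) {
  if (max(c(0, pairs$i, pairs$j)) > n_channels)
    stop("coupling pair index exceeds channel count")
  pairs$i <- as.integer(pairs$i)
  pairs$j <- as.integer(pairs$j)
  parent <- seq_len(n_channels)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (r in seq_len(nrow(pairs))) {
    a <- find(pairs$i[r]); b <- find(pairs$j[r])
    if (a != b) parent[b] <- a
  }
  roots <- vapply(seq_len(n_channels), find, integer(1))
  comps <- split(seq_len(n_channels), roots)
  comps <- comps[vapply(comps, length, integer(1)) > 1L]
  lapply(comps, function(nodes) {
    rows <- pairs$i %in% nodes | pairs$j %in% nodes
    kap <- unique(pairs$kappa[rows])
    if (length(kap) != 1L)
      stop("all coupled pairs within one connected component must share kappa")
    list(nodes = nodes, kappa = kap)
  })
}

#' Specify a synthetic two-group EEG cohort
#'
#' Defaults state the emulated study: two groups ("TC" and "control"),
#' 30 channels of the 10-20 montage at 250 Hz, 4-minute eyes-closed records.
#' Both groups carry a posterior alpha cluster (eyes-closed alpha) whose
#' per-subject strength is scaled by an individual coupling factor; the TC
#' group additionally receives the planted \code{group_effect}: extra alpha
#' coupling on frontal/temporal nodes. Reaction time is generated from the
#' subject's ground-truth weighted alpha global efficiency (equal to the mean
#' true PLV) through a linear model.
#'
#' @param n_per_group subjects per group (>= 2).
#' @param n_channels channel count (default 30; must match the montage
#'   labels).
#' @param sampling_rate_hz sampling rate (default 250).
#' @param duration_s record duration in seconds (default 240).
#' @param bands named list of \code{band_definition}s (default the four
#'   classical bands).
#' @param baseline list \code{(band, nodes, kappa)}: coupling applied to both
#'   groups. Default: alpha coupling, kappa 2, on O1/OZ/O2/P3/Pz/P4.
#' @param group_effect list \code{(band, nodes, kappa)}: additional coupling
#'   cluster applied to group "TC" only. Default: alpha coupling, kappa 1.8,
#'   on FP1/FP2/F7/F8/F3/F4/FZ/T3/T4. Set \code{kappa = 0} for a null cohort.
#' @param subject_scale_range range of the per-subject multiplicative kappa
#'   factor (individual coupling strength variability).
#' @param amplitudes named per-band oscillation amplitudes (microvolts).
#' @param noise_sd white measurement noise sd (microvolts).
#' @param rt_model list \code{(intercept_ms, slope, noise_sd_ms)} linking true
#'   weighted alpha global efficiency E to reaction time
#'   \code{rt = intercept + slope * E + noise}.
#' @param epoch_length_s epoch length the duration must accommodate.
#' @param seed master integer seed; subject s uses seed + s so subjects are
#'   independently reproducible.
#' @return list of class \code{cohort_spec}.
#' @export
cohort_spec <- function(n_per_group = 25, n_channels = 30,
                        sampling_rate_hz = 250, duration_s = 240,
                        bands = eeg_bands(),
                        baseline = list(band = "alpha",
                                        nodes = c("O1", "OZ", "O2", "P3", "Pz", "P4"),
                                        kappa = 2),
                        group_effect = list(band = "alpha",
                                            nodes = c("FP1", "FP2", "F7", "F8",
                                                      "F3", "F4", "FZ", "T3", "T4"),
                                            kappa = 1.8),
                        subject_scale_range = c(0.5, 1.5),
                        amplitudes = c(delta = 15, theta = 10, alpha = 20, beta = 8),
                        noise_sd = 5,
                        rt_model = list(intercept_ms = 520, slope = -1500,
                                        noise_sd_ms = 25),
                        epoch_length_s = 15,
                        seed = 1L) {
  if (n_per_group < 2) stop("n_per_group must be >= 2")
  mont <- montage_1020()
  if (n_channels != nrow(mont)) mont <- mont[seq_len(min(n_channels, nrow(mont))), ]
  if (n_channels > 30) stop("n_channels exceeds the 30-channel montage")
  n_epochs <- floor(duration_s / epoch_length_s)
  if (n_epochs < 1) stop("duration too short for one epoch")
  structure(list(n_per_group = n_per_group, n_channels = n_channels,
                 sampling_rate_hz = sampling_rate_hz, duration_s = duration_s,
                 bands = bands, baseline = baseline, group_effect = group_effect,
                 subject_scale_range = subject_scale_range,
                 amplitudes = amplitudes, noise_sd = noise_sd,
                 rt_model = rt_model, epoch_length_s = epoch_length_s,
                 montage = mont, seed = as.integer(seed)),
            class = "cohort_spec")
}

# per-band coupling_spec list for one subject of a given group
subject_coupling <- function(spec, group, kappa_scale) {
  mont <- spec$montage
  out <- lapply(names(spec$bands), function(bn) {
    band <- spec$bands[[bn]]
    rows <- list()
    add_cluster <- function(nodes, kappa) {
      idx <- match(nodes, mont$channel)
      idx <- idx[!is.na(idx) & idx <= spec$n_channels]
      if (length(idx) < 2 || kappa <= 0) return(NULL)
      cmb <- utils::combn(sort(idx), 2)
      data.frame(i = cmb[1, ], j = cmb[2, ], kappa = kappa)
    }
    if (!is.null(spec$baseline) && identical(spec$baseline$band, bn))
      rows <- c(rows, list(add_cluster(spec$baseline$nodes,
                                       spec$baseline$kappa * kappa_scale)))
    if (group == "TC" && !is.null(spec$group_effect) &&
        identical(spec$group_effect$band, bn))
      rows <- c(rows, list(add_cluster(spec$group_effect$nodes,
                                       spec$group_effect$kappa * kappa_scale)))
    rows <- rows[!vapply(rows, is.null, logical(1))]
    pairs <- if (length(rows)) do.call(rbind, rows) else NULL
    coupling_spec(band$center_hz, pairs,
                  background_noise_sd = 0,
                  amplitude = unname(spec$amplitudes[bn]))
  })
  names(out) <- names(spec$bands)
  out
}

# synthesize one subject's multichannel record from per-band coupling specs
synthesize_record <- function(couplings, n_channels, n_samples,
                              sampling_rate_hz, noise_sd,
                              walk_sd_shared = 0.02, walk_sd_free = 0.2) {
  x <- matrix(0, n_channels, n_samples)
  tt <- (seq_len(n_samples) - 1) / sampling_rate_hz
  for (cs in couplings) {
    comps <- coupling_components(cs$pairs, n_channels)
    in_cluster <- rep(FALSE, n_channels)
    phase <- matrix(0, n_channels, n_samples)
    blk <- jitter_block(sampling_rate_hz, cs$band_center_hz)
    for (cp in comps) {
      common <- 2 * pi * cs$band_center_hz * tt + stats::runif(1, -pi, pi) +
        cumsum(stats::rnorm(n_samples, 0, walk_sd_shared))
      for (ch in cp$nodes) {
        phase[ch, ] <- common + block_jitter(n_samples, cp$kappa, blk)
        in_cluster[ch] <- TRUE
      }
    }
    for (ch in which(!in_cluster)) {
      phase[ch, ] <- 2 * pi * cs$band_center_hz * tt +
        stats::runif(1, -pi, pi) +
        cumsum(stats::rnorm(n_samples, 0, walk_sd_free))
    }
    x <- x + cs$amplitude * cos(phase)
  }
  if (noise_sd > 0)
    x <- x + matrix(stats::rnorm(length(x), 0, noise_sd), nrow(x))
  x
}

# model-implied PLV matrix for a coupling spec (unit diagonal)
true_plv_matrix <- function(cs, n_channels) {
  m <- diag(1, n_channels)
  comps <- coupling_components(cs$pairs, n_channels)
  for (cp in comps) {
    v <- plv_von_mises(cp$kappa)
    for (a in cp$nodes) for (b in cp$nodes) if (a != b) m[a, b] <- v
  }
  m
}

# weighted global efficiency of a true-PLV graph: direct in-cluster links are
# the weighted shortest paths, so this reduces to the mean off-diagonal PLV
true_weighted_efficiency <- function(true_plv) {
  n <- nrow(true_plv)
  sum(true_plv[upper.tri(true_plv)]) * 2 / (n * (n - 1))
}

#' Simulate a two-group EEG cohort
#'
#' Generates one multichannel recording per subject plus a cohort covariate
#' table and the per-subject, per-band ground truth. Deterministic given
#' \code{spec$seed}; subject s consumes seed \code{seed + s} only, so any
#' subject can be regenerated in isolation.
#'
#' @param spec a [cohort_spec()].
#' @return list of class \code{cohort} with fields \code{recordings} (list of
#'   [eeg_recording()]), \code{table} (data.frame: subject_id, group, age,
#'   sex, rt_ms, psycap_total), and \code{ground_truth} (per subject: group,
#'   kappa_scale, per-band true PLV matrix, true weighted alpha efficiency,
#'   expected rt).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- 2L * spec$n_per_group
  groups <- rep(c("TC", "control"), each = spec$n_per_group)
  ids <- sprintf("%s%02d", ifelse(groups == "TC", "TC", "CT"),
                 c(seq_len(spec$n_per_group), seq_len(spec$n_per_group)))
  n_samples <- as.integer(round(spec$duration_s * spec$sampling_rate_hz))
  recordings <- vector("list", n)
  gt <- vector("list", n)
  rows <- vector("list", n)
  for (s in seq_len(n)) {
    set.seed(spec$seed + s)
    kscale <- stats::runif(1, spec$subject_scale_range[1], spec$subject_scale_range[2])
    age <- sample(20:24, 1)
    sex <- if (stats::runif(1) < 0.7) "M" else "F"
    couplings <- subject_coupling(spec, groups[s], kscale)
    x <- synthesize_record(couplings, spec$n_channels, n_samples,
                           spec$sampling_rate_hz, spec$noise_sd)
    recordings[[s]] <- eeg_recording(x, spec$sampling_rate_hz,
                                     spec$montage$channel, subject_id = ids[s])
    tp <- lapply(couplings, true_plv_matrix, n_channels = spec$n_channels)
    ew <- true_weighted_efficiency(tp[["alpha"]])
    rt_exp <- spec$rt_model$intercept_ms + spec$rt_model$slope * ew
    rt <- rt_exp + stats::rnorm(1, 0, spec$rt_model$noise_sd_ms)
    psycap <- stats::rnorm(1, if (groups[s] == "TC") 135 else 125, 12)
    gt[[s]] <- list(subject_id = ids[s], group = groups[s],
                    kappa_scale = kscale, true_plv = tp,
                    true_alpha_efficiency = ew, rt_expected = rt_exp)
    rows[[s]] <- data.frame(subject_id = ids[s], group = groups[s],
                            age = age, sex = sex, rt_ms = rt,
                            psycap_total = psycap, stringsAsFactors = FALSE)
  }
  structure(list(recordings = recordings,
                 table = do.call(rbind, rows),
                 ground_truth = gt, spec = spec),
            class = "cohort")
}

#' Write cohort artifacts to a directory
#'
#' Writes one recording file per subject (TSV by default, or EDF) and the
#' cohort covariate table as \code{cohort.tsv}.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @param format \code{"tsv"} or \code{"edf"}.
#' @return \code{dir}, invisibly.
#' @export
write_cohort <- function(cohort, dir, format = c("tsv", "edf")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (rec in cohort$recordings)
    write_recording(rec, file.path(dir, paste0(rec$subject_id, ".", format)))
  utils::write.table(cohort$table, file.path(dir, "cohort.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}
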