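## Preprocessing: despike -> low-pass filter -> frame rotation (actor/video)
## -> latency shift (imitator/video) -> trial segmentation. Each step is
## independently callable; preprocess_recording() applies them in the fixed
## pipeline order.

#' Preprocessing configuration
#'
#' Bundles the parameters of the kinematic cleaning pipeline. Defaults are
#' the study values: spikes flagged beyond 3 SD in the twice-differenced
#' (acceleration) trace; a bidirectional 4th-order Butterworth low-pass at
#' 15 Hz; a 13 degree in-plane rotation correcting the actor's angled board
#' in the video condition; a 111 ms video presentation latency removed from
#' the imitator; and trials defined as index-finger excursions of more than
#' 100 mm from the start marker lasting more than 5 s.
#'
#' @param spike_sd_threshold SD-unit threshold on acceleration deviations.
#' @param filter_cutoff low-pass cutoff in Hz (must be below Nyquist).
#' @param filter_order Butterworth order (per pass).
#' @param rotation_deg in-plane rotation in degrees for the video-condition
#'   actor.
#' @param video_latency_s video presentation latency in seconds, removed from
#'   the video-condition imitator.
#' @param trial_min_displacement mm the index finger must move from the start
#'   marker for samples to count as within-trial.
#' @param trial_min_duration minimum duration in seconds of a supra-threshold
#'   run to count as a trial (shorter runs are false starts).
#' @param max_trials at most this many windows are kept, in temporal order.
#' @return a list of class `preprocess_config`.
#' @export
preprocess_config <- function(spike_sd_threshold = 3, filter_cutoff = 15,
                              filter_order = 4, rotation_deg = 13,
                              video_latency_s = 0.111,
                              trial_min_displacement = 100,
                              trial_min_duration = 5, max_trials = 10) {
  cfg <- list(spike_sd_threshold = spike_sd_threshold,
              filter_cutoff = filter_cutoff, filter_order = filter_order,
              rotation_deg = rotation_deg, video_latency_s = video_latency_s,
              trial_min_displacement = trial_min_displacement,
              trial_min_duration = trial_min_duration,
              max_trials = max_trials)
  num <- vapply(cfg, function(v) is.numeric(v) && length(v) == 1L, TRUE)
  if (!all(num)) stop("all preprocessing parameters must be single numbers")
  pos <- setdiff(names(cfg), "video_latency_s")
  if (any(unlist(cfg[pos]) <= 0) || cfg$video_latency_s < 0)
    stop("preprocessing parameters must be positive")
  structure(cfg, class = "preprocess_config")
}

#' Remove single-sample electromagnetic spikes
#'
#' Electromagnetic trackers occasionally emit single-sample position glitches.
#' These stand out in the twice-differenced series (acceleration): the series
#' is double-differenced, samples whose acceleration deviates more than
#' `sd_threshold` standard deviations from the acceleration mean are flagged,
#' and each flagged sample is repaired in the original series by linear
#' interpolation across the two samples either side (the flagged sample and
#' its immediate neighbours are replaced). A single-sample spike contaminates
#' three consecutive acceleration samples, so contiguous supra-threshold runs
#' are merged and flagged at the run's largest deviation. Detection is a
#' single pass: flags are computed once from the input series.
#'
#' @param series numeric vector, length at least 7.
#' @param sd_threshold threshold in SD units (default 3).
#' @return list with `series` (cleaned) and `flagged` (integer indices of
#'   detected spikes in the original series).
#' @export
despike <- function(series, sd_threshold = 3) {
  n <- length(series)
  if (n < 7L) stop("despike needs at least 7 samples, got ", n)
  acc <- diff(diff(series))              # acc[j] is centred on sample j + 1
  s <- stats::sd(acc)
  flagged <- integer(0)
  if (is.finite(s) && s > 0) {
    dev <- abs(acc - mean(acc))
    above <- dev > sd_threshold * s
    if (any(above)) {
      r <- rle(above)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      runs <- which(r$values)
      flagged <- vapply(runs, function(k) {
        idx <- starts[k]:ends[k]
        idx[which.max(dev[idx])] + 1L   # map stencil centre to original index
      }, integer(1))
    }
  }
  out <- series
  for (i in flagged) {
    lo <- max(1L, i - 2L)
    hi <- min(n, i + 2L)
    mid <- (lo + 1L):(hi - 1L)
    out[mid] <- series[lo] + (series[hi] - series[lo]) * (mid - lo) / (hi - lo)
  }
  if (3L * length(flagged) > 0.1 * n)   # each flag repairs 3 samples
    warning(sprintf("despike repaired %d of %d samples (>10%%); series may be corrupt",
                    3L * length(flagged), n))
  list(series = out, flagged = sort(flagged))
}

# Steady state of the direct-form filter for a constant input x0: with all
# past inputs and outputs held at x0, a unity-DC-gain filter stays at x0.
filter_pass <- function(b, a, x) {
  k <- max(length(a), length(b)) - 1L
  as.numeric(signal::filter(b, a, x,
                            init.x = rep(x[1L], k), init.y = rep(x[1L], k)))
}

#' Zero-phase Butterworth low-pass filter
#'
#' Applies a Butterworth low-pass filter forward and backward (zero phase
#' shift; the amplitude response is applied twice, so the half-power cutoff
#' sees an amplitude ratio of 0.5). Edges are handled by odd-reflection
#' padding of length `3 * (order + 1)` with DC steady-state initial
#' conditions, so a constant series passes through unchanged.
#'
#' @param series numeric vector.
#' @param cutoff cutoff frequency in Hz.
#' @param order filter order per pass.
#' @param fs sampling rate in Hz.
#' @return filtered numeric vector, same length as the input.
#' @export
lowpass_filter <- function(series, cutoff = 15, order = 4, fs = 240) {
  if (cutoff >= fs / 2) stop("cutoff must be below the Nyquist frequency ", fs / 2)
  n <- length(series)
  pad <- 3L * (order + 1L)
  if (n <= pad) stop("series too short to filter: need more than ", pad, " samples")
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  head_pad <- 2 * series[1L] - series[(pad + 1L):2L]
  tail_pad <- 2 * series[n] - series[(n - 1L):(n - pad)]
  x <- c(head_pad, series, tail_pad)
  y <- filter_pass(bf$b, bf$a, x)
  y <- rev(filter_pass(bf$b, bf$a, rev(y)))
  y[(pad + 1L):(pad + n)]
}

#' In-plane rotation of position coordinates
#'
#' Rotates x/y coordinate pairs samplewise by `angle_deg` using
#' `x' = x cos(a) - y sin(a)`, `y' = y cos(a) + x sin(a)`. Used to undo the
#' 13 degree board rotation of the video-condition actor.
#'
#' @param x,y numeric vectors of equal length (mm).
#' @param angle_deg rotation angle in degrees.
#' @return list with rotated `x` and `y`.
#' @export
rotate_xy <- function(x, y, angle_deg = 13) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  a <- angle_deg * pi / 180
  list(x = x * cos(a) - y * sin(a),
       y = y * cos(a) + x * sin(a))
}

#' Remove video presentation latency
#'
#' Advances every channel of a recording by `round(latency_s * sample_rate)`
#' samples (111 ms at 240 Hz is 27 samples), so that an imitator who saw the
#' actor through a delayed video feed is aligned to what they actually saw.
#' The vacated tail is filled by repeating the final sample; length is
#' unchanged. The operation is role-agnostic; the pipeline applies it only to
#' video-condition imitators.
#'
#' @param rec a [recording()].
#' @param latency_s latency in seconds (non-negative).
#' @return a [recording()] of the same length.
#' @export
shift_latency <- function(rec, latency_s) {
  stopifnot(inherits(rec, "dyad_recording"), latency_s >= 0)
  k <- as.integer(round(latency_s * rec$sample_rate))
  n <- nrow(rec$data)
  if (k >= n) stop("latency shift of ", k, " samples exceeds recording length ", n)
  if (k == 0L) return(rec)
  out <- rec
  out$data <- rbind(rec$data[(k + 1L):n, , drop = FALSE],
                    rec$data[rep(n, k), , drop = FALSE])
  out
}

#' Segment a session into action trials
#'
#' Trials are defined by the actor's movement, not the nominal trial clock:
#' a trial is a maximal run of samples in which the index fingertip is more
#' than `trial_min_displacement` mm (3D) from the start marker, lasting more
#' than `trial_min_duration` s. Shorter excursions are false starts and are
#' discarded. At most `max_trials` windows are kept, in order. Actor windows
#' are the ones applied to the paired imitator.
#'
#' @param rec a preprocessed [recording()] with its `start_point` set.
#' @param config a [preprocess_config()].
#' @return data frame with columns `trial`, `start`, `end`: 1-based sample
#'   indices, half-open, i.e. samples `start` to `end - 1` belong to the
#'   trial.
#' @export
segment_trials <- function(rec, config = preprocess_config()) {
  stopifnot(inherits(rec, "dyad_recording"))
  fs <- rec$sample_rate
  d <- sqrt((rec$data[, "index_x"] - rec$start_point[1])^2 +
            (rec$data[, "index_y"] - rec$start_point[2])^2 +
            (rec$data[, "index_z"] - rec$start_point[3])^2)
  above <- d > config$trial_min_displacement
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths > config$trial_min_duration * fs
  if (!any(keep))
    stop(sprintf("no trials detected for %s (%s, %s/%s)", rec$person_id,
                 rec$role, rec$feedback, rec$difficulty))
  idx <- which(keep)
  if (length(idx) > config$max_trials) idx <- idx[seq_len(config$max_trials)]
  data.frame(trial = seq_along(idx),
             start = starts[idx],
             end = ends[idx] + 1L)
}

unwrap_deg <- function(x) signal::unwrap(x * pi / 180) * 180 / pi

#' Run the full preprocessing pipeline on one recording
#'
#' Applies, in order: unwrapping of orientation channels to continuous
#' angles, acceleration-based despiking ([despike()]) of every channel,
#' zero-phase Butterworth low-pass filtering ([lowpass_filter()]) of every
#' channel, the 13 degree in-plane rotation ([rotate_xy()]) of position
#' channels for the actor in the video condition, and the video-latency
#' shift ([shift_latency()]) for the imitator in the video condition.
#' Trial segmentation is separate; see [segment_trials()] and
#' [preprocess_dyad()].
#'
#' @param rec a [recording()].
#' @param config a [preprocess_config()].
#' @return a [recording()] with an attribute `despike_flags`, the named count
#'   of flagged spikes per channel.
#' @export
preprocess_recording <- function(rec, config = preprocess_config()) {
  stopifnot(inherits(rec, "dyad_recording"))
  fs <- rec$sample_rate
  dat <- rec$data
  for (ch in orientation_channels()) dat[, ch] <- unwrap_deg(dat[, ch])
  flags <- integer(ncol(dat))
  names(flags) <- colnames(dat)
  for (ch in colnames(dat)) {
    ds <- despike(dat[, ch], config$spike_sd_threshold)
    dat[, ch] <- ds$series
    flags[ch] <- length(ds$flagged)
  }
  for (ch in colnames(dat))
    dat[, ch] <- lowpass_filter(dat[, ch], config$filter_cutoff,
                                config$filter_order, fs)
  if (rec$role == "actor" && rec$feedback == "video") {
    for (tr in dyad_trackers()) {
      rot <- rotate_xy(dat[, paste0(tr, "_x")], dat[, paste0(tr, "_y")],
                       config$rotation_deg)
      dat[, paste0(tr, "_x")] <- rot$x
      dat[, paste0(tr, "_y")] <- rot$y
    }
  }
  out <- rec
  out$data <- dat
  if (rec$role == "imitator" && rec$feedback == "video")
    out <- shift_latency(out, config$video_latency_s)
  attr(out, "despike_flags") <- flags
  out
}

#' Preprocess an actor/imitator pair and segment trials
#'
#' Convenience wrapper: preprocesses both recordings with
#' [preprocess_recording()], segments trials on the cleaned actor
#' ([segment_trials()]), and returns the pair with the shared trial windows
#' (the actor's windows are applied to the imitator, since the imitator
#' starts moving with the actor).
#'
#' @param actor,imitator [recording()]s of the two roles in one crossed
#'   condition.
#' @param config a [preprocess_config()].
#' @return list with `actor`, `imitator` (cleaned recordings), `windows`
#'   (trial data frame) and `flags` (per-role despike counts).
#' @export
preprocess_dyad <- function(actor, imitator, config = preprocess_config()) {
  stopifnot(actor$role == "actor", imitator$role == "imitator")
  a <- preprocess_recording(actor, config)
  b <- preprocess_recording(imitator, config)
  if (nrow(a$data) != nrow(b$data))
    stop("actor and imitator recordings differ in length")
  w <- segment_trials(a, config)
  list(actor = a, imitator = b, windows = w,
       flags = list(actor = attr(a, "despike_flags"),
                    imitator = attr(b, "despike_flags")))
}
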