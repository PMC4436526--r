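## Lag-scanned cross-correlation coupling between actor and imitator series.
## The estimator of record is dyad_coupling(), a classed fit over all seven
## derived variables; xcorr_lagscan()/abs_max()/trial_coupling() are the
## building blocks and are exported for direct use.

#' Pearson correlation as a function of lag
#'
#' Shifts `b` relative to `a` sample by sample over lags `-max_lag` to
#' `+max_lag` and computes, at each lag, the Pearson correlation over the
#' overlapping `n - |lag|` samples, using that overlap's own means and
#' variances (no padding, no global normalisation). Positive lag means `b`
#' follows `a`: with `b[t] = a[t - k]`, the peak is at lag `+k`. Lags whose
#' overlap is shorter than `min_overlap_frac * n` samples, or whose overlap
#' has zero variance in either series, are NaN.
#'
#' @param a,b numeric vectors of equal length n > 2 (actor and imitator).
#' @param max_lag maximum lag in samples, below n.
#' @param min_overlap_frac minimum overlap as a fraction of n.
#' @return an object of class `lag_curve`: list with `lags` (samples), `r`,
#'   and `n_overlap`.
#' @export
xcorr_lagscan <- function(a, b, max_lag, min_overlap_frac = 0.5) {
  n <- length(a)
  if (length(b) != n) stop("series must have equal length")
  if (n <= 2L) stop("need more than 2 samples")
  max_lag <- as.integer(max_lag)
  if (max_lag >= n) stop("max_lag must be below the series length")
  a <- a - mean(a)              # global centring; per-lag Pearson unchanged,
  b <- b - mean(b)              # keeps the running sums well conditioned
  ca <- c(0, cumsum(a)); ca2 <- c(0, cumsum(a * a))   # prefix sums, 0-based
  cb <- c(0, cumsum(b)); cb2 <- c(0, cumsum(b * b))
  lags <- (-max_lag):max_lag
  m_min <- min_overlap_frac * n
  r <- rep(NaN, length(lags))
  n_overlap <- n - abs(lags)
  for (i in seq_along(lags)) {
    l <- lags[i]
    m <- n_overlap[i]
    if (m < m_min || m < 2L) next
    if (l >= 0L) {
      sx <- ca[m + 1L];              sx2 <- ca2[m + 1L]
      sy <- cb[n + 1L] - cb[l + 1L]; sy2 <- cb2[n + 1L] - cb2[l + 1L]
      cross <- sum(a[1:m] * b[(1L + l):n])
    } else {
      k <- -l
      sx <- ca[n + 1L] - ca[k + 1L]; sx2 <- ca2[n + 1L] - ca2[k + 1L]
      sy <- cb[m + 1L];              sy2 <- cb2[m + 1L]
      cross <- sum(a[(k + 1L):n] * b[1:m])
    }
    vx <- sx2 - sx * sx / m
    vy <- sy2 - sy * sy / m
    if (vx <= 0 || vy <= 0) next
    r[i] <- min(1, max(-1, (cross - sx * sy / m) / sqrt(vx * vy)))
  }
  if (all(is.nan(r))) stop("lag curve is undefined at every lag")
  structure(list(lags = lags, r = r, n_overlap = n_overlap),
            class = "lag_curve")
}

#' Absolute-maximum correlation and its lag
#'
#' Reads off a [xcorr_lagscan()] curve the lag maximising `|r|`. Ties are
#' broken toward the smallest `|lag|`, then toward the negative lag, so the
#' most parsimonious alignment wins.
#'
#' @param curve a `lag_curve`.
#' @param fs sampling rate in Hz, used to convert the lag to seconds.
#' @return an object of class `coupling_result`: list with `r_abs_max`,
#'   `lag_at_max_s`, `signed_r_at_max` and `lag_samples`.
#' @export
abs_max <- function(curve, fs = 240) {
  ok <- which(is.finite(curve$r))
  if (!length(ok)) stop("lag curve has no defined lags")
  ord <- ok[order(-abs(curve$r[ok]), abs(curve$lags[ok]), curve$lags[ok])]
  i <- ord[1L]
  structure(list(r_abs_max = abs(curve$r[i]),
                 lag_at_max_s = curve$lags[i] / fs,
                 signed_r_at_max = curve$r[i],
                 lag_samples = curve$lags[i]),
            class = "coupling_result")
}

#' Per-trial coupling of one dependent variable
#'
#' Applies the lag scan + absolute-maximum read-off independently within
#' each trial window and averages across trials. Trials listed in `exclude`,
#' and trials too short to scan (max lag at least the window length, or an
#' everywhere-undefined curve), are skipped before averaging.
#'
#' @param actor_dv,imitator_dv full-session derived-variable vectors.
#' @param windows trial data frame from [segment_trials()].
#' @param fs sampling rate in Hz.
#' @param max_lag_s lag scan half-width in seconds (default 5).
#' @param min_overlap_frac minimum overlap fraction, see [xcorr_lagscan()].
#' @param exclude integer trial numbers to drop before averaging.
#' @return list with `per_trial` (data frame: trial, r_abs, lag_s, signed_r),
#'   `mean_r_abs`, `mean_lag_s`, and `used` (trial numbers averaged).
#' @export
trial_coupling <- function(actor_dv, imitator_dv, windows, fs = 240,
                           max_lag_s = 5, min_overlap_frac = 0.5,
                           exclude = integer(0)) {
  stopifnot(nrow(windows) >= 1L, length(actor_dv) == length(imitator_dv))
  L <- as.integer(round(max_lag_s * fs))
  res <- data.frame(trial = windows$trial, r_abs = NA_real_,
                    lag_s = NA_real_, signed_r = NA_real_)
  for (i in seq_len(nrow(windows))) {
    if (windows$trial[i] %in% exclude) next
    sel <- windows$start[i]:(windows$end[i] - 1L)
    m <- length(sel)
    if (L >= m) {
      message("trial ", windows$trial[i], " shorter than the lag scan; skipped")
      next
    }
    cr <- tryCatch(
      abs_max(xcorr_lagscan(actor_dv[sel], imitator_dv[sel], L,
                            min_overlap_frac), fs),
      error = function(e) NULL)
    if (is.null(cr)) {
      message("trial ", windows$trial[i], " has an undefined lag curve; skipped")
      next
    }
    res$r_abs[i] <- cr$r_abs_max
    res$lag_s[i] <- cr$lag_at_max_s
    res$signed_r[i] <- cr$signed_r_at_max
  }
  used <- res$trial[is.finite(res$r_abs)]
  if (!length(used)) stop("no usable trials")
  list(per_trial = res,
       mean_r_abs = mean(res$r_abs[is.finite(res$r_abs)]),
       mean_lag_s = mean(res$lag_s[is.finite(res$lag_s)]),
       used = used)
}

#' Exploratory all-pairs coupling surface
#'
#' Applies [trial_coupling()] to every ordered pair of the 42 actor channels
#' by 42 imitator channels, yielding the mean absolute-maximum r map and the
#' mean lag map. Rows index the actor channel, columns the imitator channel,
#' both in canonical order (7 trackers by x, y, z, azimuth, elevation, roll).
#' With matched channels this surface shows a high-correlation diagonal.
#'
#' @param actor,imitator preprocessed [recording()]s.
#' @param windows trial data frame from [segment_trials()] on the actor.
#' @param max_lag_s,min_overlap_frac see [trial_coupling()].
#' @return list of class `surface_maps` with 42 x 42 matrices `r_map` and
#'   `lag_map`.
#' @export
surface_maps <- function(actor, imitator, windows, max_lag_s = 5,
                         min_overlap_frac = 0.5) {
  chans <- dyad_channels()
  r_map <- matrix(NA_real_, 42L, 42L, dimnames = list(chans, chans))
  lag_map <- r_map
  fs <- actor$sample_rate
  for (ai in chans) {
    av <- actor$data[, ai]
    for (bi in chans) {
      tc <- trial_coupling(av, imitator$data[, bi], windows, fs,
                           max_lag_s, min_overlap_frac)
      r_map[ai, bi] <- tc$mean_r_abs
      lag_map[ai, bi] <- tc$mean_lag_s
    }
  }
  structure(list(r_map = r_map, lag_map = lag_map), class = "surface_maps")
}

#' Fit the dyad coupling model
#'
#' The main entry point: takes an actor and an imitator recording of one
#' crossed condition, optionally runs the preprocessing pipeline and trial
#' segmentation ([preprocess_dyad()]), derives the seven dependent variables
#' ([derive_dvs()]), and estimates, per trial and per variable, the
#' absolute-maximum cross-correlation and its lag over a +/-`max_lag_s`
#' second scan. Per-trial correlations are Fisher-transformed before
#' averaging when `z_before_mean` is `TRUE` (the default; set `FALSE` to
#' average r first and transform the mean).
#'
#' @param actor,imitator [recording()]s with roles `"actor"` and
#'   `"imitator"`.
#' @param config a [preprocess_config()].
#' @param max_lag_s,min_overlap_frac lag scan parameters, see
#'   [trial_coupling()].
#' @param preprocess if `FALSE`, the recordings are taken as already cleaned
#'   and `windows` must be supplied.
#' @param windows optional trial data frame overriding segmentation.
#' @param exclude trial numbers to drop before averaging.
#' @param z_before_mean Fisher-transform per-trial r before averaging.
#' @return an object of class `dyad_coupling` with components `means` (one
#'   row per dependent variable: `r_abs_mean`, `z_mean`, `lag_mean_s`),
#'   `per_trial` (long data frame), `windows`, and the condition metadata.
#' @seealso [build_condition_table()], [rm_2x2_test()]
#' @export
dyad_coupling <- function(actor, imitator, config = preprocess_config(),
                          max_lag_s = 5, min_overlap_frac = 0.5,
                          preprocess = TRUE, windows = NULL,
                          exclude = integer(0), z_before_mean = TRUE) {
  stopifnot(inherits(actor, "dyad_recording"),
            inherits(imitator, "dyad_recording"),
            actor$role == "actor", imitator$role == "imitator")
  if (preprocess) {
    pp <- preprocess_dyad(actor, imitator, config)
    actor <- pp$actor; imitator <- pp$imitator
    if (is.null(windows)) windows <- pp$windows
  } else if (is.null(windows)) {
    windows <- segment_trials(actor, config)
  }
  fs <- actor$sample_rate
  adv <- derive_dvs(actor)
  bdv <- derive_dvs(imitator)
  dvs <- dyad_dvs()
  per_trial <- NULL
  means <- data.frame(dv = dvs, r_abs_mean = NA_real_, z_mean = NA_real_,
                      lag_mean_s = NA_real_)
  clipped <- 0L
  for (j in seq_along(dvs)) {
    tc <- trial_coupling(adv[, dvs[j]], bdv[, dvs[j]], windows, fs,
                         max_lag_s, min_overlap_frac, exclude)
    pt <- cbind(dv = dvs[j], tc$per_trial)
    per_trial <- rbind(per_trial, pt)
    r <- tc$per_trial$r_abs[is.finite(tc$per_trial$r_abs)]
    clipped <- clipped + sum(r >= 1)
    rcl <- pmin(r, 1 - 1e-7)
    means$r_abs_mean[j] <- mean(r)
    means$z_mean[j] <- if (z_before_mean) mean(fisher_z(rcl)) else
      fisher_z(min(mean(r), 1 - 1e-7))
    means$lag_mean_s[j] <- tc$mean_lag_s
  }
  if (clipped > 0L)
    warning(clipped, " perfect correlations clipped before the Fisher transform")
  structure(list(person_id = actor$person_id, feedback = actor$feedback,
                 difficulty = actor$difficulty, sample_rate = fs,
                 max_lag_s = max_lag_s, windows = windows,
                 per_trial = per_trial, means = means,
                 z_before_mean = z_before_mean, call = match.call()),
            class = "dyad_coupling")
}

#' @export
print.dyad_coupling <- function(x, ...) {
  cat(sprintf("Dyad coupling fit: %s, %s / %s\n", x$person_id, x$feedback,
              x$difficulty))
  cat(sprintf("  %d trials, lag scan +/- %g s at %g Hz\n",
              nrow(x$windows), x$max_lag_s, x$sample_rate))
  print(x$means, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
summary.dyad_coupling <- function(object, ...) {
  object$trial_durations_s <-
    (object$windows$end - object$windows$start) / object$sample_rate
  class(object) <- "summary.dyad_coupling"
  object
}

#' @export
print.summary.dyad_coupling <- function(x, ...) {
  cat(sprintf("Dyad coupling fit: %s, %s / %s\n", x$person_id, x$feedback,
              x$difficulty))
  cat(sprintf("  trials: %d, durations %.1f-%.1f s (median %.1f s)\n",
              nrow(x$windows), min(x$trial_durations_s),
              max(x$trial_durations_s), stats::median(x$trial_durations_s)))
  cat(sprintf("  lag scan +/- %g s; Fisher transform %s averaging\n",
              x$max_lag_s, if (x$z_before_mean) "before" else "after"))
  cat("\nCondition means per dependent variable:\n")
  print(x$means, row.names = FALSE, digits = 4)
  agg <- stats::aggregate(r_abs ~ dv, x$per_trial, stats::sd)
  names(agg)[2] <- "r_abs_sd"
  cat("\nBetween-trial SD of |r|:\n")
  print(agg, row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
coef.dyad_coupling <- function(object, ...) {
  m <- as.matrix(object$means[, c("z_mean", "lag_mean_s")])
  rownames(m) <- object$means$dv
  m
}

#' @export
plot.dyad_coupling <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(7, 4, 2, 1))
  on.exit(graphics::par(op))
  pt <- x$per_trial
  graphics::boxplot(r_abs ~ dv, pt, las = 2, ylab = "|r| at best lag",
                    xlab = "", main = paste(x$feedback, x$difficulty, sep = " / "),
                    ...)
  graphics::boxplot(lag_s ~ dv, pt, las = 2, ylab = "lag at |r| max (s)",
                    xlab = "", main = x$person_id, ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}
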