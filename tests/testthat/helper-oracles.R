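# Independent brute-force oracles, kept deliberately naive and separate from
# the package implementations they check.

# Definitional lag-scanned Pearson correlation: slice the overlap at every
# lag and call stats::cor on it.
oracle_xcorr <- function(a, b, max_lag, min_overlap_frac = 0.5) {
  n <- length(a)
  lags <- (-max_lag):max_lag
  r <- rep(NaN, length(lags))
  for (i in seq_along(lags)) {
    l <- lags[i]
    if (l >= 0) { x <- a[seq_len(n - l)]; y <- b[seq_len(n - l) + l] }
    else        { x <- a[seq_len(n + l) - l]; y <- b[seq_len(n + l)] }
    if (length(x) < min_overlap_frac * n || length(x) < 2) next
    if (stats::sd(x) == 0 || stats::sd(y) == 0) next
    r[i] <- stats::cor(x, y)
  }
  list(lags = lags, r = r)
}

# Brute-force spike scan: explicit second differences, threshold on the
# deviation from the acceleration mean, contiguous runs merged at their
# largest deviation, centre index mapped back to the original series.
oracle_spike_flags <- function(x, thr = 3) {
  n <- length(x)
  acc <- x[3:n] - 2 * x[2:(n - 1)] + x[1:(n - 2)]
  dev <- abs(acc - mean(acc))
  lim <- thr * stats::sd(acc)
  flags <- integer(0)
  j <- 1
  while (j <= length(acc)) {
    if (dev[j] > lim) {
      k <- j
      while (k < length(acc) && dev[k + 1] > lim) k <- k + 1
      run <- j:k
      flags <- c(flags, run[which.max(dev[run])] + 1L)
      j <- k + 1
    } else j <- j + 1
  }
  flags
}

# Smooth random series: integrated noise, mildly low-passed by a moving
# average so it looks like a kinematic trace.
smooth_series <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- cumsum(stats::rnorm(n))
  stats::filter(c(rep(x[1], 5), x, rep(x[n], 5)), rep(1 / 5, 5),
                sides = 2)[6:(n + 5)]
}

# A random but valid recording for I/O round trips.
random_recording <- function(n = 40, seed = 1) {
  set.seed(seed)
  dat <- matrix(stats::rnorm(n * 42, sd = 100), n, 42,
                dimnames = list(NULL, dyad_channels()))
  recording(dat, person_id = "io", sample_rate = 240,
            start_point = stats::rnorm(3))
}

# A minimal fake coupling fit for table assembly tests.
fake_fit <- function(person, feedback, difficulty, z = 1, lag = 0.5,
                     r = tanh(z)) {
  structure(list(person_id = person, feedback = feedback,
                 difficulty = difficulty, sample_rate = 240, max_lag_s = 5,
                 windows = data.frame(trial = 1, start = 1, end = 100),
                 per_trial = NULL,
                 means = data.frame(dv = dyad_dvs(), r_abs_mean = r,
                                    z_mean = z, lag_mean_s = lag),
                 z_before_mean = TRUE),
            class = "dyad_coupling")
}

# A complete 2x2 condition table for n persons, one value generator per cell.
make_table <- function(n = 12, dvs = dyad_dvs(), value = function(...) rnorm(1)) {
  grid <- expand.grid(person_id = paste0("p", seq_len(n)),
                      feedback = c("face_to_face", "video"),
                      difficulty = c("simple", "complex"),
                      dv = dvs, stringsAsFactors = FALSE)
  grid$z_mean <- mapply(value, grid$person_id, grid$feedback,
                        grid$difficulty, grid$dv)
  grid$lag_mean_s <- grid$z_mean
  grid
}
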