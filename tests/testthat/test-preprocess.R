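test_that("despike restores a constant series hit by one spike", {
  x <- rep(5, 100)
  x[50] <- x[50] + 100
  out <- despike(x)
  expect_identical(out$flagged, 50L)
  expect_true(all(abs(out$series - 5) < 1e-9))
})

test_that("despike never flags pure sinusoids", {
  # a sinusoid's acceleration is itself sinusoidal: its extremes sit at
  # sqrt(2) SD from the mean, well under the 3 SD threshold
  t <- seq(0, 2, by = 1 / 240)
  for (f in c(0.5, 2, 7, 30)) {
    out <- despike(sin(2 * pi * f * t) * 50)
    expect_identical(out$flagged, integer(0))
    expect_equal(out$series, sin(2 * pi * f * t) * 50)
  }
})

test_that("despike finds injected spikes and agrees with a brute-force scan", {
  set.seed(61)
  act <- synth_actor(n_trials = 2, trial_s = 8, rest_s = 3)
  sp <- inject_spikes(act$recording, 5, amplitude = 50 * sd(act$recording$data[, "index_y"]))
  for (ch in c("index_y", "wrist_z", "elbow_x")) {
    x <- sp$recording$data[, ch]
    out <- despike(x)
    expect_true(all(sp$spike_indices[[ch]] %in% out$flagged))
    expect_identical(out$flagged, oracle_spike_flags(x))
  }
})

test_that("despike contracts: length floor and corruption warning", {
  expect_error(despike(rnorm(6)), "at least 7")
  set.seed(1)
  x <- rnorm(100)
  x[seq(10, 60, by = 10)] <- 1000    # 6 spikes repair 18 of 100 samples
  expect_warning(out <- despike(x), "10%")
  expect_length(out$flagged, 6)
})

test_that("low-pass filter has unit DC gain and the designed rolloff", {
  expect_lt(max(abs(lowpass_filter(rep(7.3, 200)) - 7.3)), 1e-9)

  t <- seq(0, 2, by = 1 / 240)
  centre <- 150:330
  amp <- function(f) {
    y <- lowpass_filter(sin(2 * pi * f * t), cutoff = 15, order = 4, fs = 240)
    max(abs(y[centre]))
  }
  # two -3 dB passes at the cutoff: amplitude ratio 1/2
  expect_equal(amp(15), 0.5, tolerance = 0.02 / 0.5)
  # two octaves above a 4th-order cutoff, applied twice
  expect_lt(amp(60), 0.01)
  expect_error(lowpass_filter(rnorm(100), cutoff = 130, fs = 240), "Nyquist")
  expect_error(lowpass_filter(rnorm(10)), "too short")
})

test_that("rotation applies the in-plane formulas exactly", {
  r0 <- rotate_xy(0, 0, 13)
  expect_equal(c(r0$x, r0$y), c(0, 0))
  r1 <- rotate_xy(1, 0, 13)
  expect_equal(r1$x, cos(13 * pi / 180))
  expect_equal(r1$y, sin(13 * pi / 180))
  expect_equal(round(c(r1$x, r1$y), 5), c(0.97437, 0.22495))

  set.seed(71)
  x <- rnorm(100); y <- rnorm(100)
  rot <- rotate_xy(x, y, 13)
  expect_true(all(abs(sqrt(rot$x^2 + rot$y^2) - sqrt(x^2 + y^2)) < 1e-12))
  back <- rotate_xy(rot$x, rot$y, -13)
  expect_true(all(abs(back$x - x) < 1e-12))
  expect_true(all(abs(back$y - y) < 1e-12))
})

test_that("latency shift advances by the rounded sample count", {
  rec <- random_recording(n = 200, seed = 81)
  expect_identical(shift_latency(rec, 0)$data, rec$data)

  imp <- rec
  imp$data[] <- 0
  imp$data[100, ] <- 1
  shifted <- shift_latency(imp, 0.111)        # round(26.64) = 27 samples
  expect_equal(which(shifted$data[, "head_x"] == 1), 73)

  ramp <- rec
  ramp$data[] <- seq_len(200)
  sh <- shift_latency(ramp, 0.111)
  expect_equal(sh$data[1:173, "thumb_z"], 28:200)
  expect_equal(sh$data[174:200, "thumb_z"], rep(200, 27))
  expect_error(shift_latency(rec, 10), "exceeds")
})

test_that("trial segmentation keeps long excursions and drops false starts", {
  fs <- 240
  n <- 30 * fs
  dat <- matrix(0, n, 42, dimnames = list(NULL, dyad_channels()))
  away <- function(from_s, to_s) (from_s * fs):(to_s * fs)
  dat[away(3, 9), "index_x"] <- 150          # 6 s excursion: a trial
  rec <- recording(dat, start_point = c(0, 0, 0))
  w <- segment_trials(rec)
  expect_equal(nrow(w), 1)
  expect_equal(w$start, 3 * fs)
  expect_equal(w$end, 9 * fs + 1)            # half-open: run ends at 9*fs

  dat2 <- matrix(0, n, 42, dimnames = list(NULL, dyad_channels()))
  dat2[away(2, 6), "index_x"] <- 150         # 4 s false start
  dat2[away(10, 17), "index_x"] <- 150       # 7 s trial
  rec2 <- recording(dat2, start_point = c(0, 0, 0))
  w2 <- segment_trials(rec2)
  expect_equal(nrow(w2), 1)
  expect_equal(w2$start, 10 * fs)

  flat <- recording(matrix(0, 10 * fs, 42,
                           dimnames = list(NULL, dyad_channels())),
                    person_id = "flatliner", start_point = c(0, 0, 0))
  expect_error(segment_trials(flat), "no trials.*flatliner")
})

test_that("at most the first ten windows are kept", {
  fs <- 240
  n <- 12 * 12 * fs
  dat <- matrix(0, n, 42, dimnames = list(NULL, dyad_channels()))
  for (k in 0:11) dat[(k * 12 * fs + fs):(k * 12 * fs + 8 * fs), "index_y"] <- 200
  rec <- recording(dat, start_point = c(0, 0, 0))
  w <- segment_trials(rec)
  expect_equal(nrow(w), 10)
  expect_equal(w$trial, 1:10)
})

test_that("pipeline recovers ground-truth trial onsets on synthetic dyads", {
  set.seed(91)
  act <- synth_actor(n_trials = 3, trial_s = 20, rest_s = 5)
  clean <- preprocess_recording(act$recording)
  w <- segment_trials(clean)
  truth <- act$truth$trial_windows
  expect_equal(nrow(w), nrow(truth))
  expect_true(all(abs(w$start - truth$start) <= 0.25 * 240))
})

test_that("despiking a cleaned series is a no-op on smooth data", {
  t <- seq(0, 3, by = 1 / 240)
  x <- 50 * sin(2 * pi * 1.3 * t) + 20 * cos(2 * pi * 0.4 * t)
  x[c(200, 400)] <- x[c(200, 400)] + 300
  once <- despike(x)
  again <- despike(once$series)
  expect_identical(again$flagged, integer(0))
  expect_equal(again$series, once$series)
})

test_that("preprocess_recording applies role-dependent steps", {
  set.seed(95)
  d <- synth_dyad("video", "simple", true_lag_s = 0.2, noise_sd = 0,
                  n_trials = 2, trial_s = 8, rest_s = 3)
  pa <- preprocess_recording(d$actor)
  # rotation restored the task frame: the actor's rest-position index
  # finger sits at the start marker again
  rest <- 1:5
  sp <- d$actor$start_point
  expect_lt(max(abs(pa$data[rest, "index_y"] - (sp[2]))), 2)
  expect_named(attr(pa, "despike_flags"), dyad_channels())
})
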