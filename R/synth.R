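## Synthetic pegboard dyads with known ground truth. The generator emulates
## the imitation game: a 4x4 pegboard (60 mm spacing, peg heights 30/70/110/
## 150 mm front to back), an actor moving balls between adjacent pegs with
## minimum-jerk hand paths, and an imitator that is a lagged, noisy,
## gain-perturbed copy of the actor. Everything the pipeline later estimates
## (trial windows, lag, coupling degradation) is recorded as ground truth.

#' Pegboard geometry
#'
#' The imitation game board: a 4x4 grid of vertical pegs at 60 mm spacing
#' with heights 30, 70, 110 and 150 mm from the front row to the back row,
#' 40 mm balls, and a start marker off the near-right corner. Coordinates:
#' x to the right, y away from the player (front row at y = 0), z up, all in
#' mm. Pegs are numbered row-major from the front-left.
#'
#' @param start_point start-marker position; the default sits far enough
#'   from the nearest peg that the 100 mm trial-detection radius separates
#'   rest from play.
#' @return list of class `board_geometry` with `pegs` (16 x 3 matrix of peg
#'   top positions), `spacing`, `heights`, `ball_diameter`, `start_point`.
#' @export
board_geometry <- function(start_point = c(280, -80, 25)) {
  grid <- expand.grid(col = 0:3, row = 0:3)
  heights <- c(30, 70, 110, 150)
  pegs <- cbind(x = grid$col * 60, y = grid$row * 60,
                z = heights[grid$row + 1L])
  structure(list(pegs = pegs, spacing = 60, heights = heights,
                 ball_diameter = 40, start_point = start_point),
            class = "board_geometry")
}

peg_adjacent <- function(p, q) {
  pr <- (p - 1L) %/% 4L; pc <- (p - 1L) %% 4L
  qr <- (q - 1L) %/% 4L; qc <- (q - 1L) %% 4L
  abs(pr - qr) + abs(pc - qc) == 1L
}

adjacent_pegs <- function(p) {
  Filter(function(q) peg_adjacent(p, q), 1:16)
}

#' Sample a legal move sequence
#'
#' Draws the 10 ball moves of one trial. Moves are always between
#' horizontally or vertically adjacent pegs (never diagonal) into an
#' unoccupied peg. In the simple condition one ball makes all 10 moves; in
#' the complex condition all three balls are used (each at least once, 10
#' moves in total). If the walk dead-ends (a ball with no free adjacent
#' peg), the sampler restarts from a fresh random placement with a message.
#'
#' @param difficulty `"simple"` or `"complex"`.
#' @param balls integer vector of length 3: current peg of each ball
#'   (distinct, in 1..16).
#' @return list of class `move_sequence`: `moves` (data frame `ball`,
#'   `from`, `to`), `difficulty`, and `balls` (final placement). Randomness
#'   comes from the session RNG stream.
#' @export
sample_move_sequence <- function(difficulty = c("simple", "complex"),
                                 balls = sample(1:16, 3)) {
  difficulty <- match.arg(difficulty)
  stopifnot(length(balls) == 3L, !anyDuplicated(balls),
            all(balls %in% 1:16))
  for (attempt in 1:100) {
    st <- balls
    plan <- if (difficulty == "simple") rep(sample(3, 1), 10) else {
      repeat {
        p <- sample(3, 10, replace = TRUE)
        if (length(unique(p)) == 3L) break
      }
      p
    }
    moves <- data.frame(ball = integer(0), from = integer(0), to = integer(0))
    ok <- TRUE
    for (b in plan) {
      free <- setdiff(adjacent_pegs(st[b]), st)
      if (!length(free)) { ok <- FALSE; break }
      to <- if (length(free) == 1L) free else sample(free, 1)
      moves <- rbind(moves, data.frame(ball = b, from = st[b], to = to))
      st[b] <- to
    }
    if (ok)
      return(structure(list(moves = moves, difficulty = difficulty,
                            balls = st), class = "move_sequence"))
    message("move walk dead-ended; resampling from a fresh placement")
    balls <- sample(1:16, 3)
  }
  stop("could not sample a legal move sequence")
}

#' Minimum-jerk point-to-point trajectory
#'
#' The smooth reaching profile `s(tau) = 10 tau^3 - 15 tau^4 + 6 tau^5`
#' applied along the straight line from `p0` to `p1`: position starts at
#' `p0`, ends at `p1`, with zero velocity and acceleration at both ends.
#'
#' @param p0,p1 3D endpoints (mm).
#' @param duration segment duration in seconds (> 0).
#' @param fs sampling rate in Hz.
#' @return a `(round(duration * fs) + 1) x 3` matrix including both
#'   endpoints.
#' @export
min_jerk_segment <- function(p0, p1, duration, fs = 240) {
  stopifnot(duration > 0, length(p0) == 3L, length(p1) == 3L)
  n <- max(2L, as.integer(round(duration * fs)) + 1L)
  tau <- seq(0, 1, length.out = n)
  s <- 10 * tau^3 - 15 * tau^4 + 6 * tau^5
  outer(s, as.numeric(p1 - p0)) + rep(as.numeric(p0), each = n)
}

min_jerk_scalar <- function(a0, a1, n) {
  tau <- seq(0, 1, length.out = max(2L, n))
  a0 + (a1 - a0) * (10 * tau^3 - 15 * tau^4 + 6 * tau^5)
}

# Arc between two pegs: two minimum-jerk halves via a point above the
# taller endpoint (ball transports stay as low arcs over the pegs).
arc_points <- function(p0, p1, clearance = 30) {
  via <- c((p0[1] + p1[1]) / 2, (p0[2] + p1[2]) / 2,
           max(p0[3], p1[3]) + clearance)
  list(via = via)
}

smooth_noise <- function(n, sd, fs, cutoff = 6) {
  if (sd <= 0 || n < 30L) return(numeric(n))
  x <- lowpass_filter(stats::rnorm(n), cutoff = cutoff, order = 2, fs = fs)
  s <- stats::sd(x)
  if (s == 0) return(numeric(n))
  x / s * sd
}

# Two-link inverse kinematics: elbow position from shoulder and wrist paths,
# taking the elbow-below-the-line solution.
elbow_ik <- function(S, W, upper = 300, fore = 260) {
  d <- sqrt(rowSums((W - S)^2))
  if (max(d) >= upper + fore) {
    scl <- max(d) / (upper + fore) * 1.02
    warning(sprintf("wrist out of reach; arm segments scaled by %.2f", scl))
    upper <- upper * scl; fore <- fore * scl
  }
  d <- pmax(d, abs(upper - fore) + 1)
  a <- (d^2 + upper^2 - fore^2) / (2 * d)
  h <- sqrt(pmax(upper^2 - a^2, 0))
  u <- (W - S) / d
  # component of straight-down perpendicular to the shoulder-wrist line
  w <- cbind(0, 0, -1) [rep(1, nrow(S)), , drop = FALSE] - u * (-u[, 3])
  wn <- sqrt(rowSums(w^2))
  wn[wn < 1e-9] <- 1
  v <- w / wn
  S + u * a + v * h
}

build_trial <- function(balls, difficulty, trial_s, fs, board) {
  ms <- sample_move_sequence(difficulty, balls)
  pegs <- board$pegs
  grasp <- function(p) pegs[p, ] + c(0, 0, 10)   # grip centre on the ball
  # segment plan: targets for the grip position, aperture at arrival,
  # and whether the segment is an arc over the pegs
  targets <- list()
  hand_at <- NULL
  add <- function(point, ap, arc) targets[[length(targets) + 1L]] <<-
    list(p = point, ap = ap, arc = arc)
  add(grasp(ms$moves$from[1]), 40, FALSE)        # initial reach
  hand_at <- ms$moves$from[1]
  for (i in seq_len(nrow(ms$moves))) {
    mv <- ms$moves[i, ]
    if (mv$from != hand_at)                      # switch to another ball
      add(grasp(mv$from), 40, TRUE)
    add(grasp(mv$to), 40, TRUE)                  # ball transport
    hand_at <- mv$to
  }
  add(board$start_point, 10, TRUE)               # return to the start marker
  nseg <- length(targets)
  n_trial <- as.integer(round(trial_s * fs))
  motion_s <- trial_s * stats::runif(1, 0.85, 0.95)
  seg_s <- motion_s / nseg
  g <- matrix(board$start_point, nrow = 1, ncol = 3, byrow = TRUE)
  ap <- 10
  cur <- board$start_point
  for (tg in targets) {
    if (tg$arc && sum((tg$p - cur)^2) > 1e-9) {
      via <- arc_points(cur, tg$p)$via
      seg <- rbind(min_jerk_segment(cur, via, seg_s / 2, fs)[-1, , drop = FALSE],
                   min_jerk_segment(via, tg$p, seg_s / 2, fs)[-1, , drop = FALSE])
    } else {
      seg <- min_jerk_segment(cur, tg$p, seg_s, fs)[-1, , drop = FALSE]
    }
    g <- rbind(g, seg)
    ap <- c(ap, min_jerk_scalar(ap[length(ap)], tg$ap, nrow(seg) + 1L)[-1][seq_len(nrow(seg))])
    cur <- tg$p
  }
  if (nrow(g) < n_trial) {                       # hold at start until the beep
    hold <- n_trial - nrow(g)
    g <- rbind(g, matrix(board$start_point, hold, 3, byrow = TRUE))
    ap <- c(ap, rep(ap[length(ap)], hold))
  } else {
    g <- g[seq_len(n_trial), , drop = FALSE]
    ap <- ap[seq_len(n_trial)]
  }
  list(g = g, ap = ap, moves = ms)
}

#' Synthesize an actor's session recording
#'
#' Generates a full continuous session: `n_trials` trials of `trial_s`
#' seconds separated by `rest_s` second rests, during which the hand grips
#' the start marker. Within each trial the grip position follows
#' minimum-jerk ball-transport arcs over the pegs for a sampled
#' [sample_move_sequence()]; the thumb and index fingertips open and close
#' around the grip position; the wrist and little finger ride at fixed
#' offsets; the elbow follows from two-link inverse kinematics (upper arm
#' 300 mm, forearm 260 mm, shoulder essentially static 150 mm behind and
#' 400 mm above the board edge, elbow-down solution); the head drifts
#' slowly. Orientation channels are smoothed low-amplitude signals driven by
#' the hand velocity; they exist so all 42 channels are analysable, not as
#' biomechanics.
#'
#' @param board a [board_geometry()].
#' @param n_trials,trial_s,rest_s session layout (defaults 10 trials of
#'   20 s with 5 s rests).
#' @param difficulty `"simple"` or `"complex"`.
#' @param fs sampling rate in Hz.
#' @param person_id,feedback metadata stored on the recording.
#' @return list with `recording` (a [recording()], role `"actor"`) and
#'   `truth`: ground-truth `trial_windows` (the intervals the index finger
#'   is beyond the 100 mm start radius, half-open sample indices),
#'   `move_sequences`, and the session parameters.
#' @export
synth_actor <- function(board = board_geometry(), n_trials = 10, trial_s = 20,
                        rest_s = 5, difficulty = c("simple", "complex"),
                        fs = 240, person_id = "sim1",
                        feedback = c("face_to_face", "video")) {
  difficulty <- match.arg(difficulty)
  feedback <- match.arg(feedback)
  n_rest <- as.integer(round(rest_s * fs))
  g <- NULL; ap <- NULL
  moves <- list()
  balls <- sample(1:16, 3)
  for (tr in seq_len(n_trials)) {
    bt <- build_trial(balls, difficulty, trial_s, fs, board)
    balls <- bt$moves$balls
    moves[[tr]] <- bt$moves
    g <- rbind(g, bt$g); ap <- c(ap, bt$ap)
    if (tr < n_trials) {
      g <- rbind(g, matrix(board$start_point, n_rest, 3, byrow = TRUE))
      ap <- c(ap, rep(10, n_rest))
    }
  }
  n <- nrow(g)
  ux <- c(1, 0, 0)                                  # grip opening axis
  index <- g + outer(ap / 2, ux)
  thumb <- g - outer(ap / 2, ux)
  wrist <- g + matrix(c(-15, -70, -25), n, 3, byrow = TRUE)
  little <- g + matrix(c(35, -15, -5), n, 3, byrow = TRUE)
  S0 <- c(90, -150, 400)
  shoulder <- matrix(S0, n, 3, byrow = TRUE) +
    cbind(smooth_noise(n, 2, fs, 2), smooth_noise(n, 2, fs, 2),
          smooth_noise(n, 1.5, fs, 2))
  elbow <- elbow_ik(shoulder, wrist)
  head <- matrix(c(90, -400, 650), n, 3, byrow = TRUE) +
    cbind(8 * sin(2 * pi * (1:n) / (30 * fs)),
          6 * sin(2 * pi * (1:n) / (45 * fs) + 1),
          4 * sin(2 * pi * (1:n) / (25 * fs) + 2)) +
    cbind(smooth_noise(n, 1, fs, 1), smooth_noise(n, 1, fs, 1),
          smooth_noise(n, 1, fs, 1))
  pos <- list(head = head, shoulder = shoulder, elbow = elbow, wrist = wrist,
              thumb = thumb, index = index, little = little)
  dat <- matrix(NA_real_, n, 42, dimnames = list(NULL, dyad_channels()))
  bases <- c(head = 0, shoulder = 10, elbow = 20, wrist = 35, thumb = 50,
             index = 55, little = 60)
  for (tr in dyad_trackers()) {
    p <- pos[[tr]]
    dat[, paste0(tr, "_x")] <- p[, 1]
    dat[, paste0(tr, "_y")] <- p[, 2]
    dat[, paste0(tr, "_z")] <- p[, 3]
    v <- rbind(0, diff(p)) * fs
    vs <- apply(v, 2, function(col)
      lowpass_filter(col, cutoff = 3, order = 2, fs = fs))
    dat[, paste0(tr, "_azimuth")]   <- bases[tr] + 0.04 * vs[, 1] +
      smooth_noise(n, 0.5, fs, 2)
    dat[, paste0(tr, "_elevation")] <- bases[tr] / 2 + 0.04 * vs[, 2] +
      smooth_noise(n, 0.5, fs, 2)
    dat[, paste0(tr, "_roll")]      <- -bases[tr] / 3 + 0.04 * vs[, 3] +
      smooth_noise(n, 0.5, fs, 2)
  }
  disp <- sqrt(rowSums((index - matrix(board$start_point, n, 3,
                                       byrow = TRUE))^2))
  r <- rle(disp > 100)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values & r$lengths > 5 * fs)
  truth_windows <- data.frame(trial = seq_along(keep), start = starts[keep],
                              end = ends[keep] + 1L)
  rec <- recording(dat, person_id = person_id, role = "actor",
                   feedback = feedback, difficulty = difficulty,
                   sample_rate = fs, start_point = board$start_point)
  list(recording = rec,
       truth = list(trial_windows = truth_windows, move_sequences = moves,
                    n_trials = n_trials, trial_s = trial_s, rest_s = rest_s))
}

#' Synthesize an imitator from an actor recording
#'
#' The imitator model: every channel of the actor, delayed by `true_lag_s`,
#' scaled by `gain` about the channel mean, plus low-pass-filtered Gaussian
#' noise of standard deviation `noise_sd` (filtered at 6 Hz so the copying
#' error itself looks kinematic). Samples vacated by the delay are padded
#' with the actor's rest posture (the first/last sample). With zero lag,
#' zero noise and unit gain the imitator is the actor.
#'
#' @param actor an actor [recording()].
#' @param true_lag_s imitator delay in seconds, `|lag| <= 5`; rounded to a
#'   whole number of samples.
#' @param noise_sd copying-noise SD (mm for position channels; the same
#'   numeric SD, in degrees, is used for orientation channels).
#' @param gain amplitude scaling about each channel mean.
#' @param person_id metadata label.
#' @return list with `recording` (role `"imitator"`) and `truth` (the
#'   requested lag, the effective sample-rounded lag, noise SD, gain).
#' @export
synth_imitator <- function(actor, true_lag_s, noise_sd = 0, gain = 1,
                           person_id = paste0(actor$person_id, "_im")) {
  stopifnot(inherits(actor, "dyad_recording"), abs(true_lag_s) <= 5)
  fs <- actor$sample_rate
  k <- as.integer(round(true_lag_s * fs))
  n <- nrow(actor$data)
  if (abs(k) >= n) stop("lag exceeds recording length")
  dat <- actor$data
  if (k > 0) {
    dat <- rbind(actor$data[rep(1L, k), , drop = FALSE],
                 actor$data[1:(n - k), , drop = FALSE])
  } else if (k < 0) {
    dat <- rbind(actor$data[(-k + 1L):n, , drop = FALSE],
                 actor$data[rep(n, -k), , drop = FALSE])
  }
  if (gain != 1)
    dat <- sweep(sweep(dat, 2, colMeans(dat)) * gain, 2, colMeans(dat), `+`)
  if (noise_sd > 0)
    for (j in seq_len(ncol(dat)))
      dat[, j] <- dat[, j] + smooth_noise(n, noise_sd, fs)
  rec <- recording(dat, person_id = person_id, role = "imitator",
                   feedback = actor$feedback, difficulty = actor$difficulty,
                   sample_rate = fs, start_point = actor$start_point)
  list(recording = rec,
       truth = list(true_lag_s = true_lag_s, effective_lag_s = k / fs,
                    noise_sd = noise_sd, gain = gain))
}

#' Inject single-sample spikes
#'
#' Adds single-sample offsets of the given amplitude at random positions in
#' every channel, at least 5 samples from the series edges and from each
#' other, emulating electromagnetic tracker glitches. Returns the spiked
#' recording and the injected indices per channel as ground truth for
#' despiking tests.
#'
#' @param rec a [recording()].
#' @param n_per_series spikes per channel.
#' @param amplitude spike amplitude (added as-is).
#' @return list with `recording` and `spike_indices` (named list of integer
#'   vectors).
#' @export
inject_spikes <- function(rec, n_per_series, amplitude) {
  stopifnot(inherits(rec, "dyad_recording"), n_per_series >= 0, amplitude > 0)
  n <- nrow(rec$data)
  if (n_per_series == 0L)
    return(list(recording = rec, spike_indices =
                  stats::setNames(rep(list(integer(0)), 42), dyad_channels())))
  if (n_per_series * 5L > n - 10L)
    stop("too many spikes for the spacing constraint")
  out <- rec
  idx <- list()
  for (ch in colnames(rec$data)) {
    pick <- integer(0)
    for (tries in 1:1000) {
      cand <- sample(6:(n - 5L), 1)
      if (all(abs(cand - pick) >= 5L)) pick <- c(pick, cand)
      if (length(pick) == n_per_series) break
    }
    if (length(pick) < n_per_series) stop("could not place spikes with spacing")
    out$data[pick, ch] <- out$data[pick, ch] + amplitude
    idx[[ch]] <- sort(pick)
  }
  list(recording = out, spike_indices = idx)
}

#' Feedback-condition scenario parameters
#'
#' The generator's default study conditions per feedback condition: the
#' imitator's behavioural lag is set to the observed grip-position mean lag
#' of each condition (0.67 s face-to-face, 0.79 s video), and copying noise
#' is larger under video (12 mm vs 5 mm), encoding the degraded coupling of
#' mediated feedback. Gain is 1.
#'
#' @param feedback `"face_to_face"` or `"video"`.
#' @return list with `true_lag_s`, `noise_sd`, `gain`.
#' @export
dyad_scenario <- function(feedback = c("face_to_face", "video")) {
  feedback <- match.arg(feedback)
  if (feedback == "face_to_face")
    list(true_lag_s = 0.67, noise_sd = 5, gain = 1)
  else
    list(true_lag_s = 0.79, noise_sd = 12, gain = 1)
}

#' Generate a complete synthetic dyad
#'
#' Builds the actor and imitator recordings of one crossed condition with
#' full ground truth. In the video condition the recordings carry the two
#' artefacts the preprocessing pipeline is built to remove: the actor's
#' position channels are stored in the 13-degree-rotated board frame (the
#' pipeline's rotation restores the task frame), and the imitator's
#' behavioural lag is increased by the 111 ms video presentation latency
#' (the pipeline's latency shift removes it).
#'
#' @param feedback,difficulty the crossed condition.
#' @param person_id session label.
#' @param true_lag_s,noise_sd,gain imitator model parameters; `NULL` takes
#'   the [dyad_scenario()] default for the feedback condition.
#' @param n_trials,trial_s,rest_s,fs session layout, see [synth_actor()].
#' @param board a [board_geometry()].
#' @param seed optional integer; if given, seeds the session RNG.
#' @return list with `actor`, `imitator` (recordings) and `truth` (lag,
#'   noise, gain, trial windows, move sequences).
#' @export
synth_dyad <- function(feedback = c("face_to_face", "video"),
                       difficulty = c("simple", "complex"),
                       person_id = "sim1", true_lag_s = NULL, noise_sd = NULL,
                       gain = 1, n_trials = 10, trial_s = 20, rest_s = 5,
                       fs = 240, board = board_geometry(), seed = NULL) {
  feedback <- match.arg(feedback)
  difficulty <- match.arg(difficulty)
  if (!is.null(seed)) set.seed(seed)
  sc <- dyad_scenario(feedback)
  if (is.null(true_lag_s)) true_lag_s <- sc$true_lag_s
  if (is.null(noise_sd)) noise_sd <- sc$noise_sd
  act <- synth_actor(board, n_trials, trial_s, rest_s, difficulty, fs,
                     person_id, feedback)
  lag_total <- true_lag_s + if (feedback == "video") 0.111 else 0
  im <- synth_imitator(act$recording, lag_total, noise_sd, gain)
  actor_rec <- act$recording
  if (feedback == "video") {
    # store the actor in the rotated board frame; preprocessing undoes it
    a <- 13 * pi / 180
    for (tr in dyad_trackers()) {
      x <- actor_rec$data[, paste0(tr, "_x")]
      y <- actor_rec$data[, paste0(tr, "_y")]
      actor_rec$data[, paste0(tr, "_x")] <- x * cos(a) + y * sin(a)
      actor_rec$data[, paste0(tr, "_y")] <- y * cos(a) - x * sin(a)
    }
  }
  list(actor = actor_rec, imitator = im$recording,
       truth = c(im$truth,
                 list(behavioural_lag_s = true_lag_s,
                      trial_windows = act$truth$trial_windows,
                      move_sequences = act$truth$move_sequences)))
}
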