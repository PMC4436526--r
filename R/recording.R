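#' @keywords internal
"_PACKAGE"

## Canonical channel layout -------------------------------------------------

#' Tracker and degree-of-freedom layout
#'
#' The recording system tracks seven points per person (head, shoulder, elbow,
#' wrist, thumb tip, index-finger tip, little-finger tip), each with six
#' degrees of freedom: position x, y, z in millimetres and orientation
#' azimuth, elevation, roll in degrees. All recordings in this package are
#' laid out in this canonical order, 7 x 6 = 42 channels.
#'
#' @return `dyad_trackers()` and `dyad_dofs()` return character vectors;
#'   `dyad_channels()` returns the 42 canonical `<tracker>_<dof>` names.
#' @export
dyad_trackers <- function() {
  c("head", "shoulder", "elbow", "wrist", "thumb", "index", "little")
}

#' @rdname dyad_trackers
#' @export
dyad_dofs <- function() {
  c("x", "y", "z", "azimuth", "elevation", "roll")
}

#' @rdname dyad_trackers
#' @export
dyad_channels <- function() {
  as.vector(t(outer(dyad_trackers(), dyad_dofs(), paste, sep = "_")))
}

position_channels <- function() {
  as.vector(t(outer(dyad_trackers(), c("x", "y", "z"), paste, sep = "_")))
}

orientation_channels <- function() {
  setdiff(dyad_channels(), position_channels())
}

## Recording ----------------------------------------------------------------

#' Construct a dyad recording
#'
#' A `dyad_recording` holds one person's full-session motion time series:
#' a numeric matrix with one row per sample and the 42 canonical channels as
#' columns (see [dyad_channels()]), together with the session metadata needed
#' downstream (role in the dyad, feedback and difficulty condition, sampling
#' rate, and the 3D position of the board's start marker in the same frame as
#' the position channels).
#'
#' @param data numeric matrix, n x 42, with canonical column names in any
#'   order (they are reordered to canonical order).
#' @param person_id label for the participant/session.
#' @param role `"actor"` or `"imitator"`.
#' @param feedback `"face_to_face"` or `"video"`.
#' @param difficulty `"simple"` or `"complex"`.
#' @param sample_rate sampling rate in Hz.
#' @param start_point numeric length-3, start-marker position in mm.
#' @return an object of class `dyad_recording`.
#' @export
recording <- function(data, person_id = "p1", role = c("actor", "imitator"),
                      feedback = c("face_to_face", "video"),
                      difficulty = c("simple", "complex"),
                      sample_rate = 240,
                      start_point = c(0, 0, 0)) {
  role <- match.arg(role)
  feedback <- match.arg(feedback)
  difficulty <- match.arg(difficulty)
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("recording data must be numeric")
  chans <- dyad_channels()
  if (is.null(colnames(data))) {
    if (ncol(data) != 42L)
      stop("unnamed recording data must have exactly 42 columns")
    colnames(data) <- chans
  }
  missing_tr <- unique(sub("_[a-z]+$", "",
                           setdiff(chans, colnames(data))))
  if (length(missing_tr))
    stop("missing channels for tracker(s): ", paste(missing_tr, collapse = ", "))
  data <- data[, chans, drop = FALSE]
  if (nrow(data) < 1L) stop("recording must contain at least one sample")
  if (!all(is.finite(data)))
    stop("recording contains non-finite values (sample ",
         which(!apply(is.finite(data), 1L, all))[1L], ")")
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0)
    stop("sample_rate must be a single positive number")
  if (length(start_point) != 3L || !all(is.finite(start_point)))
    stop("start_point must be a finite 3D position")
  structure(
    list(person_id = as.character(person_id), role = role,
         feedback = feedback, difficulty = difficulty,
         sample_rate = as.numeric(sample_rate),
         start_point = as.numeric(start_point),
         data = data),
    class = "dyad_recording")
}

#' @export
print.dyad_recording <- function(x, ...) {
  cat(sprintf("<dyad_recording> %s (%s), %s / %s\n", x$person_id, x$role,
              x$feedback, x$difficulty))
  cat(sprintf("  %d samples at %g Hz (%.1f s), 42 channels\n",
              nrow(x$data), x$sample_rate, nrow(x$data) / x$sample_rate))
  cat(sprintf("  start point: (%.1f, %.1f, %.1f) mm\n",
              x$start_point[1], x$start_point[2], x$start_point[3]))
  invisible(x)
}

#' @export
length.dyad_recording <- function(x) nrow(x$data)

## File I/O -----------------------------------------------------------------

#' Read and write dyad recordings as wide CSV
#'
#' One recording is one wide CSV: a `t` column in seconds plus one column per
#' canonical channel, named `<tracker>_<dof>` (position channels in mm,
#' orientation channels in degrees). The header row is mandatory; column
#' order in the file is free. An optional leading comment line
#' `# start_point,<x>,<y>,<z>` carries the start-marker position, so a write
#' followed by a read reproduces the recording exactly. Values are written
#' with 17 significant digits, enough to round-trip doubles losslessly.
#'
#' @param path file path.
#' @param person_id,role,feedback,difficulty,sample_rate,start_point session
#'   metadata; see [recording()]. `sample_rate` and `start_point` default to
#'   values stored in the file (falling back to 240 Hz / origin).
#' @param scale multiplicative factor applied to position channels on read,
#'   for devices whose native unit is not mm (e.g. `10` for cm).
#' @return `read_recording()` returns a [recording()]; `write_recording()`
#'   returns `path` invisibly.
#' @export
read_recording <- function(path, person_id = "p1",
                           role = c("actor", "imitator"),
                           feedback = c("face_to_face", "video"),
                           difficulty = c("simple", "complex"),
                           sample_rate = NULL, start_point = NULL,
                           scale = 1) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1L)
  if (grepl("^#\\s*start_point", first)) {
    sp <- suppressWarnings(as.numeric(strsplit(first, ",")[[1]][-1]))
    if (length(sp) == 3L && all(is.finite(sp)) && is.null(start_point))
      start_point <- sp
  }
  nf <- utils::count.fields(path, sep = ",", comment.char = "#")
  if (length(unique(nf)) > 1L) {
    bad <- which(nf != nf[1L])[1L]
    stop("ragged row in ", path, ": line ", bad + sum(grepl("^#", first)),
         " has ", nf[bad], " fields, expected ", nf[1L])
  }
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE,
                        colClasses = "character")
  if (nrow(df) == 0L) stop("empty recording file: ", path)
  chans <- dyad_channels()
  missing_tr <- unique(sub("_[a-z]+$", "", setdiff(chans, names(df))))
  if (length(missing_tr))
    stop("file ", path, " is missing columns for tracker(s): ",
         paste(missing_tr, collapse = ", "))
  mat <- matrix(NA_real_, nrow(df), length(chans), dimnames = list(NULL, chans))
  for (ch in chans) {
    v <- suppressWarnings(as.numeric(df[[ch]]))
    bad <- which(is.na(v) | !is.finite(v))
    if (length(bad))
      stop("non-numeric or non-finite value in column '", ch,
           "' of ", path, " at data line ", bad[1L],
           " ('", df[[ch]][bad[1L]], "')")
    mat[, ch] <- v
  }
  if (scale != 1) {
    pos <- position_channels()
    mat[, pos] <- mat[, pos] * scale
  }
  if (is.null(sample_rate)) {
    tcol <- suppressWarnings(as.numeric(df[["t"]]))
    sample_rate <- if (!is.null(tcol) && nrow(df) > 1L &&
                       all(is.finite(tcol))) {
      1 / stats::median(diff(tcol))
    } else 240
  }
  recording(mat, person_id = person_id, role = role, feedback = feedback,
            difficulty = difficulty, sample_rate = sample_rate,
            start_point = if (is.null(start_point)) c(0, 0, 0) else start_point)
}

#' @rdname read_recording
#' @param rec a [recording()].
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "dyad_recording"))
  if (!all(is.finite(rec$data)))
    stop("refusing to write recording with non-finite values")
  n <- nrow(rec$data)
  t <- (seq_len(n) - 1L) / rec$sample_rate
  body <- cbind(t, rec$data)
  txt <- matrix(sprintf("%.17g", body), nrow = n)
  lines <- c(
    sprintf("# start_point,%.17g,%.17g,%.17g",
            rec$start_point[1], rec$start_point[2], rec$start_point[3]),
    paste(c("t", colnames(rec$data)), collapse = ","),
    apply(txt, 1L, paste, collapse = ","))
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) stop("cannot write ", path, ": ",
                                          conditionMessage(e)))
  invisible(path)
}

## Config -------------------------------------------------------------------

#' Read a run configuration file
#'
#' Configuration is a YAML file with optional sections `preprocess` (passed to
#' [preprocess_config()]), `coupling` (e.g. `max_lag_s`, `min_overlap_frac`),
#' `io` (e.g. `scale`, `sample_rate`) and `seed`.
#'
#' @param path YAML file path.
#' @return a named list of configuration sections.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config file must contain a mapping: ", path)
  cfg
}
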