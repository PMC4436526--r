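## Derived kinematic variables: arm joint angles q1-q3, grip aperture and
## grip position. All are samplewise maps of the (cleaned) marker positions,
## so trial windows index into them unchanged.

vec3 <- function(rec, tracker) {
  rec$data[, paste0(tracker, c("_x", "_y", "_z")), drop = FALSE]
}

clamp1 <- function(x) pmin(1, pmax(-1, x))

#' Arm joint angles from shoulder, elbow and wrist markers
#'
#' Three angles summarise the arm configuration at each sample, all in
#' degrees via the arc cosine (range 0 to 180):
#' \describe{
#'   \item{q1}{shoulder elevation: the angle between the elbow-to-shoulder
#'     vector and the downward vertical through the shoulder,
#'     `acos((z_S - z_E) / |ES|)`. An elbow directly below the shoulder gives
#'     0.}
#'   \item{q2}{horizontal shoulder direction: the angle, in the horizontal
#'     plane, between the elbow-to-shoulder displacement and the y axis,
#'     `acos((y_S - y_E) / |EO|)` where `|EO|` is the horizontal (x, y)
#'     magnitude of the shoulder-elbow displacement. An elbow displaced
#'     purely in -y gives 0; purely in +x gives 90.}
#'   \item{q3}{elbow angle by the cosine rule on the shoulder/elbow/wrist
#'     triangle, `acos((|SW|^2 - |ES|^2 - |EW|^2) / (2 |ES| |EW|))`. This
#'     convention gives 0 for a fully extended (collinear) arm and 90 for a
#'     right angle at the elbow, i.e. 180 minus the triangle's interior
#'     elbow angle.}
#' }
#' Cosine arguments are clamped to [-1, 1] to absorb floating-point
#' round-off at collinear configurations. Samples with a zero-length
#' shoulder-elbow, elbow-wrist or horizontal displacement are degenerate and
#' yield NaN; more than 1% degenerate samples triggers a warning.
#'
#' @param S,E,W n x 3 matrices of shoulder, elbow and wrist positions (mm).
#' @return data frame with columns `q1`, `q2`, `q3` in degrees.
#' @export
joint_angles <- function(S, E, W) {
  S <- as.matrix(S); E <- as.matrix(E); W <- as.matrix(W)
  stopifnot(ncol(S) == 3L, ncol(E) == 3L, ncol(W) == 3L,
            nrow(S) == nrow(E), nrow(E) == nrow(W))
  ES2 <- rowSums((S - E)^2)
  EW2 <- rowSums((W - E)^2)
  SW2 <- rowSums((W - S)^2)
  ES <- sqrt(ES2)
  EW <- sqrt(EW2)
  EOh <- sqrt((S[, 1] - E[, 1])^2 + (S[, 2] - E[, 2])^2)
  q1 <- ifelse(ES > 0, acos(clamp1((S[, 3] - E[, 3]) / ES)), NaN)
  q2 <- ifelse(EOh > 0, acos(clamp1((S[, 2] - E[, 2]) / EOh)), NaN)
  q3 <- ifelse(ES > 0 & EW > 0,
               acos(clamp1((SW2 - ES2 - EW2) / (2 * ES * EW))), NaN)
  bad <- sum(!is.finite(q1) | !is.finite(q2) | !is.finite(q3))
  if (bad > 0.01 * nrow(S))
    warning(sprintf("%d of %d samples degenerate in joint_angles", bad, nrow(S)))
  data.frame(q1 = q1 * 180 / pi, q2 = q2 * 180 / pi, q3 = q3 * 180 / pi)
}

#' Grip aperture and grip position
#'
#' `grip_aperture()` is the samplewise 3D Euclidean distance between the
#' index-finger and thumb tips (mm), the primary prehension variable.
#' `grip_position()` is their samplewise midpoint per axis, a proxy for the
#' transported object's location.
#'
#' @param index,thumb n x 3 matrices of fingertip positions (mm).
#' @return `grip_aperture()`: numeric vector of distances;
#'   `grip_position()`: n x 3 matrix with columns `x`, `y`, `z`.
#' @export
grip_aperture <- function(index, thumb) {
  index <- as.matrix(index); thumb <- as.matrix(thumb)
  stopifnot(ncol(index) == 3L, ncol(thumb) == 3L, nrow(index) == nrow(thumb))
  sqrt(rowSums((index - thumb)^2))
}

#' @rdname grip_aperture
#' @export
grip_position <- function(index, thumb) {
  index <- as.matrix(index); thumb <- as.matrix(thumb)
  stopifnot(ncol(index) == 3L, ncol(thumb) == 3L, nrow(index) == nrow(thumb))
  out <- (index + thumb) / 2
  colnames(out) <- c("x", "y", "z")
  out
}

#' The seven dependent variables of a recording
#'
#' Computes, per sample, the seven kinematic variables the condition analysis
#' is run on: joint angles `q1`, `q2`, `q3` (degrees), grip `aperture` (mm)
#' and grip position `grip_x`, `grip_y`, `grip_z` (mm). All columns have
#' exactly the recording's length, so trial windows index into them directly.
#' Derived variables are intended to be computed after preprocessing.
#'
#' @param rec a (preprocessed) [recording()].
#' @return an n x 7 numeric matrix.
#' @export
derive_dvs <- function(rec) {
  stopifnot(inherits(rec, "dyad_recording"))
  ja <- joint_angles(vec3(rec, "shoulder"), vec3(rec, "elbow"),
                     vec3(rec, "wrist"))
  gp <- grip_position(vec3(rec, "index"), vec3(rec, "thumb"))
  out <- cbind(q1 = ja$q1, q2 = ja$q2, q3 = ja$q3,
               aperture = grip_aperture(vec3(rec, "index"), vec3(rec, "thumb")),
               grip_x = gp[, "x"], grip_y = gp[, "y"], grip_z = gp[, "z"])
  out
}

#' @rdname derive_dvs
#' @export
dyad_dvs <- function() c("q1", "q2", "q3", "aperture", "grip_x", "grip_y", "grip_z")
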