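# Angle definitions.
#
# All operations assume math coordinates (y up) as produced by
# read_keypoint_table(). Points are length-2 vectors c(x, y) or n x 2
# matrices (vectorized over frames). All angles in degrees.
#
# Conventions:
#  * roll-plane tail angle (rear view): 0 = tail straight down,
#    90 = horizontal on the animal's right, 180 = straight up,
#    270 = horizontal left; range [0, 360).
#  * yaw-plane angles (top view) are signed, in (-180, 180]; each
#    function documents its own zero and positive direction.

deg <- function(rad) rad * 180 / pi

as_pts <- function(p) if (is.matrix(p)) p else matrix(p, ncol = 2)

check_distinct <- function(a, b, what) {
  d <- rowSums((as_pts(a) - as_pts(b))^2)
  if (any(d == 0))
    stop("undefined angle: coincident points in ", what,
         " (frame ", which(d == 0)[1], ")")
}

# signed angle (deg, (-180,180]) from reference vector `ref` to vectors `v`
signed_angle_from <- function(v, ref) {
  v <- as_pts(v); ref <- as_pts(ref)
  if (nrow(ref) == 1 && nrow(v) > 1) ref <- ref[rep(1, nrow(v)), , drop = FALSE]
  cr <- ref[, 1] * v[, 2] - ref[, 2] * v[, 1]
  dt <- ref[, 1] * v[, 1] + ref[, 2] * v[, 2]
  a <- deg(atan2(cr, dt))
  ifelse(a <= -180, a + 360, a)
}

#' Wrap angles to (-180, 180]
#' @param x Angles in degrees.
#' @return Wrapped angles.
#' @export
wrap180 <- function(x) {
  out <- (x + 180) %% 360 - 180
  ifelse(out == -180, 180, out)
}

#' Unwrap an angle series (remove 360-degree jumps)
#' @param x Angle series in degrees.
#' @return Continuous (unwrapped) series; first sample unchanged.
#' @export
unwrap_deg <- function(x) {
  if (length(x) < 2) return(x)
  d <- wrap180(diff(x))
  cumsum(c(x[1], d))
}

#' Construct an angle trace
#'
#' @param name One of \code{roll_tail}, \code{yaw_tail}, \code{hip},
#'   \code{back}, \code{front}, \code{tail_on_body}.
#' @param values Angle per frame, degrees.
#' @param frame_rate Frames per second.
#' @param convention Free-text tag describing the zero/positive direction.
#' @return An object of class \code{angle_trace}.
#' @export
angle_trace <- function(name, values,
                        frame_rate = 300, convention = "") {
  name <- match.arg(name, c("roll_tail", "yaw_tail", "hip", "back",
                            "front", "tail_on_body"))
  values <- as.numeric(values)
  if (any(!is.finite(values))) stop("angle trace must be finite")
  structure(list(name = name, values = values, frame_rate = frame_rate,
                 convention = convention), class = "angle_trace")
}

#' @export
print.angle_trace <- function(x, ...) {
  cat("Angle trace '", x$name, "': ", length(x$values), " frames @ ",
      x$frame_rate, " fps", sep = "")
  if (nzchar(x$convention)) cat(" [", x$convention, "]", sep = "")
  cat("\n  range ", round(min(x$values), 2), "..",
      round(max(x$values), 2), " deg\n", sep = "")
  invisible(x)
}

#' Roll-plane tail angle (rear view)
#'
#' Angle of the initial tail segment with respect to vertical, as seen from
#' the posterior camera: 0 deg = tail pointing straight down, 90 deg =
#' horizontal on the animal's right, 180 deg = tail pointing up; range
#' [0, 360).
#'
#' @param tail_base,tail_seg Points (c(x, y) or n x 2 matrices) in rear-view
#'   math coordinates: the tail base marker and the first post-base tail
#'   marker.
#' @return Angle(s) in degrees, [0, 360).
#' @export
roll_tail_angle <- function(tail_base, tail_seg) {
  check_distinct(tail_base, tail_seg, "roll_tail_angle")
  b <- as_pts(tail_base); s <- as_pts(tail_seg)
  v <- s - b
  (deg(atan2(v[, 1], -v[, 2]))) %% 360
}

#' Yaw-plane tail angle (top view)
#'
#' Signed angle of the initial tail segment with respect to the backward
#' ridge direction: 0 deg = tail pointing straight back along the ridge;
#' positive = deviation toward -y (clockwise from straight back); range
#' (-180, 180].
#'
#' @param tail_base,tail_seg Top-view points.
#' @param ridge_axis Unit vector of the forward ridge direction
#'   (default \code{c(1, 0)}).
#' @return Signed angle(s) in degrees.
#' @export
yaw_tail_angle <- function(tail_base, tail_seg, ridge_axis = c(1, 0)) {
  check_distinct(tail_base, tail_seg, "yaw_tail_angle")
  v <- as_pts(tail_seg) - as_pts(tail_base)
  signed_angle_from(v, -ridge_axis)
}

#' Hip angle (rear view)
#'
#' Alignment of the line connecting the two hip markers with respect to
#' vertical: 0 deg = vertical, 90 deg = horizontal; range [0, 180].
#'
#' @param left_hip,right_hip Rear-view points.
#' @return Angle(s) in degrees, [0, 180].
#' @export
hip_angle <- function(left_hip, right_hip) {
  check_distinct(left_hip, right_hip, "hip_angle")
  d <- as_pts(right_hip) - as_pts(left_hip)
  abs(deg(atan2(d[, 1], d[, 2])))
}

#' Signed hip inclination (rear view)
#'
#' Like \code{\link{hip_angle}} but keeping the side of the tilt:
#' 90 = horizontal, above 90 = animal's right hip lower than the left.
#' This is the trace differentiated to obtain body angular velocity.
#'
#' @inheritParams hip_angle
#' @return Angle(s) in degrees, (0, 180) for non-degenerate hip lines.
#' @export
hip_angle_signed <- function(left_hip, right_hip) {
  check_distinct(left_hip, right_hip, "hip_angle")
  d <- as_pts(right_hip) - as_pts(left_hip)
  # direct the hip line toward the animal's right (+x); angle from vertical
  flip <- d[, 1] < 0
  d[flip, ] <- -d[flip, , drop = FALSE]
  deg(atan2(d[, 1], d[, 2]))
}

#' Back angle (top view)
#'
#' Signed angle at the tail base between the forward ridge-parallel line
#' and the tail-base-to-centroid vector: 0 deg = hind body aligned straight
#' back along the ridge.
#'
#' @param tail_base,centroid Top-view points.
#' @param ridge_axis Forward ridge unit vector.
#' @return Signed angle(s) in degrees, (-180, 180].
#' @export
back_angle <- function(tail_base, centroid, ridge_axis = c(1, 0)) {
  check_distinct(tail_base, centroid, "back_angle")
  v <- as_pts(centroid) - as_pts(tail_base)
  signed_angle_from(v, ridge_axis)
}

#' Front angle (top view)
#'
#' Signed angle between the centroid-to-nose direction and the ridge axis:
#' 0 deg = head aligned straight ahead along the ridge.
#'
#' @param centroid,nose Top-view points.
#' @param ridge_axis Forward ridge unit vector.
#' @return Signed angle(s) in degrees, (-180, 180].
#' @export
front_angle <- function(centroid, nose, ridge_axis = c(1, 0)) {
  check_distinct(centroid, nose, "front_angle")
  v <- as_pts(nose) - as_pts(centroid)
  signed_angle_from(v, ridge_axis)
}

#' Tail-on-body angle
#'
#' Frame-wise difference between the yaw-plane tail angle and the back
#' angle, wrapped to (-180, 180]: 0 deg = tail aligned straight back along
#' the body axis.
#'
#' @param tail_yaw,back \code{angle_trace} objects (or numeric vectors) of
#'   equal length and frame rate.
#' @return An \code{angle_trace} named \code{tail_on_body}.
#' @export
tail_on_body_angle <- function(tail_yaw, back) {
  tv <- if (inherits(tail_yaw, "angle_trace")) tail_yaw$values else tail_yaw
  bv <- if (inherits(back, "angle_trace")) back$values else back
  if (length(tv) != length(bv))
    stop("shape error: tail and back traces differ in length (",
         length(tv), " vs ", length(bv), ")")
  fr <- if (inherits(tail_yaw, "angle_trace")) tail_yaw$frame_rate else 300
  angle_trace("tail_on_body", wrap180(tv - bv), frame_rate = fr,
              convention = "0 = tail straight back along body axis")
}

#' Instantaneous angular velocity
#'
#' Central-difference gradient of the unwrapped angle trace, scaled to
#' deg/s; endpoints use one-sided differences.
#'
#' @param angle An \code{angle_trace}, or a numeric vector of degrees (then
#'   \code{frame_rate} must be given).
#' @param frame_rate Frames per second (taken from the trace if omitted).
#' @return Numeric vector, deg/s, same length as the input.
#' @export
angular_velocity <- function(angle, frame_rate = NULL) {
  v <- if (inherits(angle, "angle_trace")) angle$values else as.numeric(angle)
  if (is.null(frame_rate))
    frame_rate <- if (inherits(angle, "angle_trace")) angle$frame_rate
                  else stop("frame_rate required for plain numeric input")
  n <- length(v)
  if (n < 2) stop("length error: need at least 2 frames")
  u <- unwrap_deg(v)
  g <- numeric(n)
  g[1] <- u[2] - u[1]
  g[n] <- u[n] - u[n - 1]
  if (n > 2) g[2:(n - 1)] <- (u[3:n] - u[1:(n - 2)]) / 2
  g * frame_rate
}

#' Classify trial laterality (ipsilateral vs contralateral tilt)
#'
#' The side on which the tail is held at tilt onset is read from the
#' roll-plane tail angle (angles in (0, 180) = right, (180, 360) = left).
#' A tilt toward the tail side is ipsilateral (IL), away is contralateral
#' (CL).
#'
#' @param roll_tail_at_onset Roll-plane tail angle (deg, [0, 360)) at tilt
#'   onset.
#' @param tilt_direction \code{"left"} or \code{"right"}.
#' @return List with \code{tail_side} and \code{label} ("IL" or "CL").
#' @export
classify_laterality <- function(roll_tail_at_onset, tilt_direction) {
  tilt_direction <- match.arg(tilt_direction, c("left", "right"))
  a <- roll_tail_at_onset %% 360
  if (a == 0 || a == 180)
    stop("unclassifiable: tail exactly vertical at tilt onset")
  tail_side <- if (a < 180) "right" else "left"
  list(tail_side = tail_side,
       label = if (tail_side == tilt_direction) "IL" else "CL")
}

#' Mirror-normalize a set of angle traces
#'
#' Trials are pooled across left- and right-held tails by reflecting
#' left-tail trials so the tail side is canonically "right". Under the
#' mirror: roll angles map to 360 - theta (mod 360), signed yaw-plane
#' angles to -theta, and the signed hip inclination to 180 - theta; the
#' folded hip angle is invariant. Applying the mirror twice is the
#' identity.
#'
#' @param traces Named list of \code{angle_trace} objects (any subset of
#'   the six angle names, plus optionally \code{hip_signed} as numeric).
#' @return The mirrored list.
#' @export
mirror_angle_traces <- function(traces) {
  out <- traces
  for (nm in names(traces)) {
    tr <- traces[[nm]]
    vals <- if (inherits(tr, "angle_trace")) tr$values else tr
    new <- switch(nm,
      roll_tail = (360 - vals) %% 360,
      hip = vals,
      hip_signed = 180 - vals,
      yaw_tail = , back = , front = , tail_on_body = wrap180(-vals),
      stop("unknown trace name: ", nm))
    if (inherits(tr, "angle_trace")) out[[nm]]$values <- new
    else out[[nm]] <- new
  }
  out
}
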