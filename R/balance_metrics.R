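# Ridge-traversing performance metrics from the top-view body centroid.
#
# The centroid approximates the centre of mass (CoM); the base of support
# (BoS) is the region between the ridge edges. Lateral offset is measured
# from the ridge midline (meta$ridge_midline_px) along top-view y.

lateral_offset_mm <- function(centroid, meta) {
  (centroid$y - meta$ridge_midline_px) * meta$mm_per_pixel[["top"]]
}

#' Trial-level traversing speed
#'
#' Forward distance covered by the centroid divided by the time taken:
#' (last - first forward coordinate over the visible frames, in mm) /
#' elapsed time.
#'
#' @param centroid A \code{centroid_trace} (top view).
#' @param meta A \code{trial_meta}.
#' @param exclude_stops If \code{TRUE}, stop-episode time (see
#'   \code{\link{detect_stops}}) is removed from the denominator.
#' @param stop_threshold mm/s threshold used when \code{exclude_stops}.
#' @return Speed in mm/s.
#' @export
traversing_speed <- function(centroid, meta, exclude_stops = FALSE,
                             stop_threshold = 1) {
  vis <- which(centroid$visible)
  if (length(vis) < 2) stop("traversing speed undefined: < 2 visible frames")
  dx_mm <- (centroid$x[vis[length(vis)]] - centroid$x[vis[1]]) *
    meta$mm_per_pixel[["top"]]
  t_s <- (vis[length(vis)] - vis[1]) / centroid$frame_rate
  if (exclude_stops) {
    st <- detect_stops(forward_speed(centroid, meta), centroid$frame_rate,
                       threshold = stop_threshold)
    t_s <- max(t_s - st$total_duration_s, 1 / centroid$frame_rate)
  }
  dx_mm / t_s
}

#' Instantaneous forward speed of the centroid
#'
#' Central-difference gradient of the smoothed forward coordinate, in mm/s.
#' Used for stop detection; the trial-level traversing speed is computed
#' from endpoint displacement instead, and the two are kept distinct.
#'
#' @param centroid A \code{centroid_trace}.
#' @param meta A \code{trial_meta}.
#' @param smooth_window Hanning window (frames) applied before
#'   differentiation.
#' @return Numeric vector, mm/s (signed; forward is positive).
#' @export
forward_speed <- function(centroid, meta, smooth_window = 10) {
  x_mm <- centroid$x * meta$mm_per_pixel[["top"]]
  if (length(x_mm) >= smooth_window)
    x_mm <- hanning_smooth(x_mm, smooth_window)
  n <- length(x_mm)
  g <- numeric(n)
  g[1] <- x_mm[2] - x_mm[1]; g[n] <- x_mm[n] - x_mm[n - 1]
  if (n > 2) g[2:(n - 1)] <- (x_mm[3:n] - x_mm[1:(n - 2)]) / 2
  g * centroid$frame_rate
}

#' Detect complete-stop episodes
#'
#' Maximal runs of frames whose instantaneous forward speed falls below the
#' threshold (complete stopping is conventionally defined as forward speed
#' below 1 mm/s).
#'
#' @param speed Instantaneous forward speed, mm/s.
#' @param frame_rate Frames per second.
#' @param threshold Speed threshold, mm/s (> 0; default 1).
#' @return List with \code{n_episodes}, \code{total_duration_s} and
#'   \code{episodes} (data.frame: start, end, duration_s). May be empty.
#' @export
detect_stops <- function(speed, frame_rate = 300, threshold = 1) {
  stopifnot(threshold > 0)
  below <- speed < threshold
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  sel <- r$values
  eps <- data.frame(start = starts[sel], end = ends[sel],
                    duration_s = r$lengths[sel] / frame_rate)
  list(n_episodes = nrow(eps), total_duration_s = sum(eps$duration_s),
       episodes = eps)
}

#' Time the CoM spends outside the base of support
#'
#' Total duration over visible frames with |lateral offset| strictly
#' greater than half the ridge width.
#'
#' @param centroid A \code{centroid_trace}.
#' @param meta A \code{trial_meta}.
#' @return Duration in seconds.
#' @export
time_outside_bos <- function(centroid, meta) {
  off <- abs(lateral_offset_mm(centroid, meta))
  sum(off[centroid$visible] > meta$ridge_width / 2) / centroid$frame_rate
}

#' CoM lateral movement
#'
#' Mean absolute distance of the centroid from the ridge midline, in mm,
#' over visible frames.
#'
#' @inheritParams time_outside_bos
#' @return Mean absolute lateral offset, mm.
#' @export
lateral_movement <- function(centroid, meta) {
  mean(abs(lateral_offset_mm(centroid, meta))[centroid$visible])
}

#' CoM centrality
#'
#' Lateral distance of the centroid normalized by the ridge half-width:
#' 1 = centroid on the midline, 0 = on the edge; offsets beyond the edge
#' clip at 0. The trial value is the mean over visible frames.
#'
#' @inheritParams time_outside_bos
#' @return Centrality in [0, 1].
#' @export
centrality <- function(centroid, meta) {
  off <- abs(lateral_offset_mm(centroid, meta))
  per_frame <- pmax(0, 1 - off / (meta$ridge_width / 2))
  mean(per_frame[centroid$visible])
}

#' Full balance-performance report for a trial
#'
#' Computes the five traversing-performance metrics: traversing speed,
#' stop episodes, time the CoM is outside the BoS, lateral movement and
#' centrality; a manually counted slip total can be attached as a label.
#'
#' @inheritParams time_outside_bos
#' @param slip_count Optional integer label (manual slip count).
#' @param stop_threshold mm/s threshold for stop detection.
#' @return An object of class \code{balance_report} (a one-row data.frame).
#' @export
balance_report <- function(centroid, meta, slip_count = NA_integer_,
                           stop_threshold = 1) {
  st <- detect_stops(forward_speed(centroid, meta), centroid$frame_rate,
                     threshold = stop_threshold)
  out <- data.frame(
    animal_id = meta$animal_id,
    trial_id = if (is.null(meta$trial_id)) NA_character_ else meta$trial_id,
    ridge_width = meta$ridge_width,
    traversing_speed = traversing_speed(centroid, meta),
    traversing_speed_excl_stops = traversing_speed(centroid, meta,
      exclude_stops = TRUE, stop_threshold = stop_threshold),
    n_stops = st$n_episodes,
    stop_duration_s = st$total_duration_s,
    time_outside_bos_s = time_outside_bos(centroid, meta),
    lateral_movement_mm = lateral_movement(centroid, meta),
    centrality = centrality(centroid, meta),
    slip_count = slip_count)
  class(out) <- c("balance_report", class(out))
  out
}
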