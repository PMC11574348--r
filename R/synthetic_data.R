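# Synthetic two-view ridge-crossing trials with known ground truth.
#
# The generator emulates the statistical structure the analysis assumes:
# step-locked sinusoidal paw/hip/tail oscillations with a shared per-stride
# "vigor" gain, a side-held tail posture, tilt-evoked stereotyped tail
# swings with a minimum-jerk angular profile, centroid forward progress
# with lateral wander, Gaussian pixel noise and likelihood dropouts.

# minimum-jerk position profile: 0 at t<=0, 1 at t>=D, C2-smooth in between
minjerk <- function(t, D) {
  tau <- pmin(pmax(t / D, 0), 1)
  10 * tau^3 - 15 * tau^4 + 6 * tau^5
}

# default width -> posture maps: narrower ridges evoke larger tail/hip
# oscillations and a lower-held (more horizontal) tail
width_key <- function(width) {
  ref <- c(4, 5, 8, 10, 45)
  as.character(ref[which.min(abs(ref - width))])
}
TAIL_MEAN_ROLL_MAP <- c("4" = 70, "5" = 75, "8" = 95, "10" = 100, "45" = 110)
TAIL_OSC_AMP_MAP <- c("4" = 12, "5" = 10, "8" = 7, "10" = 5, "45" = 3)

#' Simulation configuration
#'
#' Defaults reflect the study conditions: 300 fps recording, 4 Hz stride,
#' tilt-evoked tail swings peaking at 2.2 rotations/s with a 0.16 s time
#' to peak (body 0.12 s), anti-phase tail-hip oscillation, and ridge
#' widths of 4-45 mm.
#'
#' @param ridge_width Ridge width, mm.
#' @param ridge_length Ridge length, mm.
#' @param frame_rate Frames per second.
#' @param trial_duration Trial length, s.
#' @param stride_frequency Stride rate, Hz.
#' @param forward_speed Centroid forward speed, mm/s.
#' @param tail_side Side the tail is held on, \code{"left"}/\code{"right"}.
#' @param tail_mean_roll Mean roll-plane tail angle, deg, expressed for a
#'   right-held tail (mirrored internally for left); default from a
#'   width-dependent map (below 90 deg for widths <= 5 mm).
#' @param tail_osc_amplitude Roll-plane tail oscillation amplitude, deg;
#'   default from a width-dependent map (larger on narrower ridges).
#' @param hip_osc_amplitude Hip oscillation amplitude, deg.
#' @param tail_hip_phase Phase of the hip oscillation relative to the tail
#'   oscillation, rad (default pi: anti-phase).
#' @param tilt A \code{\link{tilt_profile}} or \code{NULL}.
#' @param swing_peak_speed Peak tail swing speed during a tilt response,
#'   rotations/s.
#' @param tail_time_to_peak Tail time to peak position after tilt onset, s.
#' @param body_time_to_peak Hip time to peak deflection after tilt onset, s.
#' @param hip_tilt_deflection Hip deflection amplitude on tilt, deg.
#' @param wander_amp Lateral centroid wander amplitude, mm.
#' @param vigor_sd S.d. of the shared per-stride amplitude gain.
#' @param noise_sd Gaussian pixel noise s.d.
#' @param dropout_rate Per-sample likelihood-dropout probability in [0, 1).
#' @param slip_rate Per-stride slip probability (label only).
#' @param lead_invisible Frames before the centroid becomes visible.
#' @param seed Integer RNG seed; same seed, same trial.
#' @return An object of class \code{sim_config}.
#' @export
sim_config <- function(ridge_width = 5, ridge_length = 500,
                       frame_rate = 300, trial_duration = 3,
                       stride_frequency = 4, forward_speed = 150,
                       tail_side = c("right", "left"),
                       tail_mean_roll = NULL, tail_osc_amplitude = NULL,
                       hip_osc_amplitude = 6, tail_hip_phase = pi,
                       tilt = NULL, swing_peak_speed = 2.2,
                       tail_time_to_peak = 0.16, body_time_to_peak = 0.12,
                       hip_tilt_deflection = 14, wander_amp = 1.5,
                       vigor_sd = 0.3, noise_sd = 1, dropout_rate = 0.02,
                       slip_rate = 0.05, lead_invisible = 0, seed = 1) {
  tail_side <- match.arg(tail_side)
  key <- width_key(ridge_width)
  if (is.null(tail_mean_roll)) tail_mean_roll <- TAIL_MEAN_ROLL_MAP[[key]]
  if (is.null(tail_osc_amplitude))
    tail_osc_amplitude <- TAIL_OSC_AMP_MAP[[key]]
  stopifnot(ridge_width > 0, frame_rate > 0, trial_duration > 0,
            stride_frequency > 0, dropout_rate >= 0, dropout_rate < 1,
            swing_peak_speed > 0, tail_time_to_peak > 0)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate one ridge-crossing trial
#'
#' Generates rear- and top-view keypoint tables (tail base and two tail
#' markers, hips, hind paws, nose), a top-view centroid trace, trial
#' metadata, and the ground truth used by the validation tests. All
#' randomness is governed by \code{config$seed}.
#'
#' During a tilt, the rhythmic oscillation is smoothly gated off and the
#' tail performs a minimum-jerk swing away from its held side whose
#' amplitude follows from the configured peak speed and time to peak
#' (peak velocity of a minimum-jerk stroke = 1.875 A / D); contralateral
#' tilts evoke the same peak speed over a range shortened by ridge
#' contact.
#'
#' @param config A \code{\link{sim_config}}.
#' @return List with \code{top}, \code{rear} (\code{keypoint_table}s),
#'   \code{centroid} (\code{centroid_trace}), \code{meta}
#'   (\code{trial_meta}) and \code{truth} (list; see Details).
#' @export
simulate_trial <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cf <- config
  set.seed(cf$seed)
  fps <- cf$frame_rate
  n <- round(cf$trial_duration * fps)
  t <- (seq_len(n) - 1) / fps
  f <- cf$stride_frequency
  mmpx <- 0.5                      # mm per pixel, both views
  side_sign <- if (cf$tail_side == "right") 1 else -1

  # shared stride phase and per-stride vigor gain (common to tail and hip)
  phase <- stats::runif(1, 0, 2 * pi)
  n_strides <- ceiling(cf$trial_duration * f) + 2
  gk <- pmin(pmax(stats::rnorm(n_strides + 1, 1, cf$vigor_sd), 0.3), 1.7)
  g <- stats::spline(x = (0:n_strides) / f, y = gk, xout = t)$y

  # tilt response profiles (canonical right-held tail)
  swing <- numeric(n); hipdef <- numeric(n); gate <- rep(1, n)
  yawswing <- numeric(n)
  onset_frame <- NA_integer_
  lat <- NULL
  if (!is.null(cf$tilt)) {
    tp <- cf$tilt
    onset_frame <- tp$onset
    t0 <- (onset_frame - 1) / fps
    lat <- if (tp$direction == cf$tail_side) "IL" else "CL"
    Tp <- cf$tail_time_to_peak
    A <- 360 * cf$swing_peak_speed * Tp / 1.875
    if (lat == "CL") { A <- 0.6 * A; Tp <- 0.6 * Tp }  # range limited, same speed
    t_ret <- 0.30
    tr <- t - t0
    # canonical swing: away from the held side, i.e. upward over the body
    sw_dir <- 1
    swing <- sw_dir * A * (minjerk(tr, Tp) - minjerk(tr - Tp, t_ret))
    hip_dir <- if (tp$direction == "right") 1 else -1
    Tb <- cf$body_time_to_peak
    hipdef <- hip_dir * cf$hip_tilt_deflection *
      (minjerk(tr, Tb) - minjerk(tr - Tb, 0.25))
    yawswing <- -40 * (minjerk(tr, Tp) - minjerk(tr - Tp, t_ret))
    # gate the rhythmic oscillation off during the response
    resp_len <- Tp + t_ret
    gate <- 1 - minjerk(tr, 0.05) + minjerk(tr - resp_len, 0.1)
  }

  # --- ground-truth angle traces (canonical right-held tail) ---
  osc <- cf$tail_osc_amplitude * g * gate * sin(2 * pi * f * t + phase)
  roll_canon <- cf$tail_mean_roll + osc + swing
  hip_osc <- cf$hip_osc_amplitude * g * gate *
    sin(2 * pi * f * t + phase + cf$tail_hip_phase)
  hip_signed_true <- 90 + hip_osc + hipdef
  yaw_canon <- 25 + 0.6 * cf$tail_osc_amplitude * g * gate *
    sin(2 * pi * f * t + phase) + yawswing

  roll_true <- if (side_sign == 1) roll_canon %% 360
               else (360 - roll_canon) %% 360
  yaw_true <- side_sign * yaw_canon

  # --- top view ---
  x0 <- 60
  speed_px <- cf$forward_speed / mmpx
  wander_px <- (cf$wander_amp / mmpx) *
    (0.7 * sin(2 * pi * 0.6 * t + stats::runif(1, 0, 2 * pi)) +
     0.3 * sin(2 * pi * 1.3 * t + stats::runif(1, 0, 2 * pi)))
  cen_x <- x0 + speed_px * t
  cen_y <- wander_px
  base_top_x <- cen_x - 50
  base_top_y <- cen_y * 0.6
  back_true <- back_angle(cbind(base_top_x, base_top_y),
                          cbind(cen_x, cen_y))
  # positive yaw = deviation toward -y (the animal's right in the top view)
  yaw_rad <- yaw_true * pi / 180
  seg_top <- 50
  mid_top_x <- base_top_x - seg_top * cos(yaw_rad)
  mid_top_y <- base_top_y - seg_top * sin(yaw_rad)
  tip_top_x <- base_top_x - 2 * seg_top * cos(0.9 * yaw_rad)
  tip_top_y <- base_top_y - 2 * seg_top * sin(0.9 * yaw_rad)
  nose_x <- cen_x + 44
  nose_y <- cen_y + 4 * sin(2 * pi * 0.8 * t + stats::runif(1, 0, 2 * pi))
  front_true <- front_angle(cbind(cen_x, cen_y), cbind(nose_x, nose_y))
  stride_amp_px <- 15 / mmpx / 2   # 15 mm step amplitude peak-to-peak
  lpaw_x <- base_top_x + 10 + stride_amp_px * sin(2 * pi * f * t + phase)
  rpaw_x <- base_top_x + 10 + stride_amp_px *
    sin(2 * pi * f * t + phase + pi)
  lpaw_y <- cen_y + 12
  rpaw_y <- cen_y - 12

  # step events: peaks of the contralateral (to the tail) paw oscillation
  contra_phase <- if (cf$tail_side == "right") 0 else pi
  k <- 0:ceiling(f * cf$trial_duration + 1)
  t_pk <- (pi / 2 - phase - contra_phase + 2 * pi * k) / (2 * pi * f)
  ev <- round(t_pk[t_pk >= 0 & t_pk <= t[n]] * fps) + 1
  ev <- ev[ev >= 1 & ev <= n]

  # --- rear view (x lateral, +x = animal's right; y up) ---
  hipc_y <- 40
  roll_rad <- roll_true * pi / 180
  base_r_x <- 0.4 * (cen_y - mean(cen_y))  # slight sway follows the body
  base_r_y <- 16
  seg_r <- 60
  mid_r_x <- base_r_x + seg_r * sin(roll_rad)
  mid_r_y <- base_r_y - seg_r * cos(roll_rad)
  tip_dev <- wrap180(roll_true - (if (side_sign == 1) cf$tail_mean_roll
                                  else 360 - cf$tail_mean_roll))
  tip_rad <- ((if (side_sign == 1) cf$tail_mean_roll
               else 360 - cf$tail_mean_roll) + 0.85 * tip_dev) * pi / 180
  tip_r_x <- base_r_x + 2 * seg_r * sin(tip_rad)
  tip_r_y <- base_r_y - 2 * seg_r * cos(tip_rad)
  hs_rad <- hip_signed_true * pi / 180
  hip_half <- 20
  lhip_x <- base_r_x - hip_half * sin(hs_rad)
  lhip_y <- hipc_y - hip_half * cos(hs_rad)
  rhip_x <- base_r_x + hip_half * sin(hs_rad)
  rhip_y <- hipc_y + hip_half * cos(hs_rad)
  lpaw_r_x <- -20 + 2 * sin(2 * pi * f * t + phase)
  rpaw_r_x <- 20 + 2 * sin(2 * pi * f * t + phase + pi)
  lpaw_r_y <- 4 + 1.5 * pmax(0, sin(2 * pi * f * t + phase))
  rpaw_r_y <- 4 + 1.5 * pmax(0, sin(2 * pi * f * t + phase + pi))

  # slips (labels only): one candidate per stride
  slip_frames <- ev[stats::runif(length(ev)) < cf$slip_rate]

  noisy <- function(m) m + stats::rnorm(length(m), 0, cf$noise_sd)
  mk_table <- function(view, coords) {
    p <- length(coords)
    x <- vapply(coords, function(cc) noisy(cc$x), numeric(n))
    y <- vapply(coords, function(cc) noisy(cc$y), numeric(n))
    lik <- matrix(stats::runif(n * p, 0.95, 1), n, p)
    drop <- matrix(stats::runif(n * p) < cf$dropout_rate, n, p)
    lik[drop] <- stats::runif(sum(drop), 0.2, 0.85)
    x[drop] <- x[drop] + stats::rnorm(sum(drop), 0, 20 * cf$noise_sd + 5)
    y[drop] <- y[drop] + stats::rnorm(sum(drop), 0, 20 * cf$noise_sd + 5)
    colnames(x) <- names(coords)
    keypoint_table(view, x, y, lik, fps)
  }
  top <- mk_table("top", list(
    nose = list(x = nose_x, y = nose_y),
    tail_base = list(x = base_top_x, y = base_top_y),
    tail_mid = list(x = mid_top_x, y = mid_top_y),
    tail_tip = list(x = tip_top_x, y = tip_top_y),
    left_hind_paw = list(x = lpaw_x, y = lpaw_y),
    right_hind_paw = list(x = rpaw_x, y = rpaw_y)))
  rear <- mk_table("rear", list(
    tail_base = list(x = base_r_x, y = rep(base_r_y, n)),
    tail_mid = list(x = mid_r_x, y = mid_r_y),
    tail_tip = list(x = tip_r_x, y = tip_r_y),
    left_hip = list(x = lhip_x, y = lhip_y),
    right_hip = list(x = rhip_x, y = rhip_y),
    left_hind_paw = list(x = lpaw_r_x, y = lpaw_r_y),
    right_hind_paw = list(x = rpaw_r_x, y = rpaw_r_y)))

  vis <- rep(TRUE, n)
  if (cf$lead_invisible > 0) vis[seq_len(min(cf$lead_invisible, n))] <- FALSE
  cen <- centroid_trace(ifelse(vis, cen_x, NA), ifelse(vis, cen_y, NA),
                        vis, fps)

  meta <- trial_meta(animal_id = "sim", ridge_width = cf$ridge_width,
                     ridge_length = cf$ridge_length, tilt = cf$tilt,
                     mm_per_pixel = c(top = mmpx, rear = mmpx),
                     ridge_midline_px = 0)

  grad <- function(v) {
    d <- numeric(n)
    d[1] <- v[2] - v[1]; d[n] <- v[n] - v[n - 1]
    d[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / 2
    d * fps
  }
  truth <- list(
    step_event_frames = ev,
    stride_frequency = f,
    roll = roll_true, yaw = yaw_true, hip_signed = hip_signed_true,
    back = back_true, front = front_true,
    tail_on_body = wrap180(yaw_true - back_true),
    omega_tail_deg_s = grad(unwrap_deg(roll_true)),
    omega_hip_deg_s = grad(hip_signed_true),
    tilt_onset = onset_frame, laterality = lat,
    slip_frames = slip_frames, tail_side = cf$tail_side,
    vigor = g, config = cf)
  list(top = top, rear = rear, centroid = cen, meta = meta, truth = truth)
}

#' Simulate a cohort of trials and write it to disk
#'
#' Generates \code{n_animals} x widths x trial types (tilt / no tilt) x
#' \code{trials_per_condition} trials with small per-animal parameter
#' jitter and a rotated (Latin-square-style) condition order, writing
#' keypoint CSVs, centroid CSVs, per-trial ground-truth JSON and a YAML
#' manifest.
#'
#' @param out_dir Output directory (created if needed).
#' @param n_animals Number of simulated animals.
#' @param trials_per_condition Trials per animal per condition.
#' @param widths Ridge widths, mm.
#' @param tilt_types Character vector from \code{c("none", "tilt")}.
#' @param tilt_amplitude,tilt_duration Tilt ramp parameters.
#' @param seed Master seed; per-trial seeds are derived from it.
#' @param jitter_sd S.d. of the per-animal multiplicative parameter jitter
#'   (0 = all animals identical).
#' @param ... Further arguments forwarded to \code{\link{sim_config}}.
#' @return Path to the manifest YAML, invisibly; the manifest is also
#'   returned as attribute \code{"manifest"}.
#' @export
simulate_cohort <- function(out_dir, n_animals = 15,
                            trials_per_condition = 3,
                            widths = c(4, 5, 8, 10),
                            tilt_types = c("none", "tilt"),
                            tilt_amplitude = 20, tilt_duration = 0.190,
                            seed = 1, jitter_sd = 0.05, ...) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  conds <- expand.grid(width = widths, type = tilt_types,
                       rep = seq_len(trials_per_condition),
                       stringsAsFactors = FALSE)
  trials <- list()
  idx <- 0L
  for (a in seq_len(n_animals)) {
    animal <- sprintf("m%02d", a)
    jit <- function() if (jitter_sd > 0) stats::rnorm(1, 1, jitter_sd) else 1
    aj <- list(amp = jit(), speed = jit(), hip = jit(), fwd = jit())
    tail_side <- if (stats::runif(1) < 0.5) "left" else "right"
    ord <- ((seq_len(nrow(conds)) + a - 2) %% nrow(conds)) + 1  # rotated order
    for (ci in ord) {
      idx <- idx + 1L
      cond <- conds[ci, ]
      trial_id <- sprintf("%s_w%02d_%s_r%d", animal, cond$width,
                          cond$type, cond$rep)
      tseed <- (seed * 10007L + idx * 131L) %% .Machine$integer.max
      tilt <- NULL
      if (cond$type == "tilt") {
        dirn <- if (stats::runif(1) < 0.5) "left" else "right"
        onset <- sample(280:420, 1)
        tilt <- tilt_profile(tilt_amplitude, tilt_duration, dirn, onset)
      }
      key <- width_key(cond$width)
      cf <- sim_config(
        ridge_width = cond$width, tail_side = tail_side,
        tail_mean_roll = TAIL_MEAN_ROLL_MAP[[key]],
        tail_osc_amplitude = TAIL_OSC_AMP_MAP[[key]] * aj$amp,
        hip_osc_amplitude = 6 * aj$hip,
        swing_peak_speed = 2.2 * aj$speed,
        forward_speed = 150 * aj$fwd,
        tilt = tilt, lead_invisible = sample(0:10, 1),
        seed = tseed, ...)
      sim <- simulate_trial(cf)
      f_top <- file.path(out_dir, paste0(trial_id, "_top.csv"))
      f_rear <- file.path(out_dir, paste0(trial_id, "_rear.csv"))
      f_cen <- file.path(out_dir, paste0(trial_id, "_centroid.csv"))
      f_truth <- file.path(out_dir, paste0(trial_id, "_truth.json"))
      write_keypoint_table(sim$top, f_top)
      write_keypoint_table(sim$rear, f_rear)
      utils::write.csv(data.frame(x = sim$centroid$x, y = sim$centroid$y,
                                  visible = sim$centroid$visible),
                       f_cen, row.names = FALSE)
      tr_json <- sim$truth
      tr_json$config <- NULL
      jsonlite::write_json(tr_json, f_truth, auto_unbox = TRUE, digits = NA,
                           null = "null")
      trials[[idx]] <- list(
        trial_id = trial_id, animal_id = animal,
        top = basename(f_top), rear = basename(f_rear),
        centroid = basename(f_cen), truth = basename(f_truth),
        ridge_width = cond$width, tail_side = tail_side,
        tilt_present = !is.null(tilt),
        tilt_direction = if (is.null(tilt)) "none" else tilt$direction,
        tilt_amplitude = if (is.null(tilt)) 0 else tilt$amplitude,
        tilt_duration = if (is.null(tilt)) 0 else tilt$duration,
        tilt_onset = if (is.null(tilt)) NA else tilt$onset,
        slip_count = length(sim$truth$slip_frames),
        seed = tseed)
    }
  }
  manifest <- list(seed = seed, n_animals = n_animals,
                   frame_rate = 300, mm_per_pixel = 0.5,
                   trials = trials)
  mf <- file.path(out_dir, "manifest.yaml")
  yaml::write_yaml(manifest, mf)
  attr(mf, "manifest") <- manifest
  invisible(mf)
}
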