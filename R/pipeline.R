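# Per-trial analysis and cohort-level orchestration.

#' Read a centroid trace CSV
#'
#' Expects columns \code{x}, \code{y}, \code{visible}.
#'
#' @param path CSV path.
#' @param frame_rate Frames per second.
#' @return A \code{centroid_trace}.
#' @export
read_centroid_csv <- function(path, frame_rate = 300) {
  d <- utils::read.csv(path)
  centroid_trace(d$x, d$y, as.logical(d$visible), frame_rate)
}

#' Analyze one ridge-crossing trial
#'
#' The full per-trial pipeline: likelihood conditioning, Hanning
#' smoothing of all coordinate series, alignment of the two views on
#' first centroid visibility, extraction of the time-centred analysis
#' window, the six angle traces (mirror-normalized so the tail side is
#' canonically right; raw signed traces retained), angular velocities,
#' step-event detection on the contralateral hind paw, balance metrics,
#' and the rod/cylinder momentum traces with window totals for tilt
#' trials.
#'
#' @param top,rear \code{keypoint_table}s for the two views.
#' @param centroid A \code{centroid_trace} (top view).
#' @param meta A \code{trial_meta}.
#' @param cutoff Likelihood cutoff (default 0.9).
#' @param smooth_window Hanning window, frames (default 10, i.e. 33 ms at
#'   300 fps).
#' @param center_n Centred analysis window length, samples (default 500).
#' @param model A \code{\link{body_model}}.
#' @param response_window Post-tilt response window, s (default 0.5).
#' @param stop_threshold Stop-detection threshold, mm/s (default 1).
#' @param pert_variant Perturbation inertia variant, see
#'   \code{\link{perturbation_momentum}}.
#' @param momentum_mode \code{"signed"} or \code{"absolute"} integration
#'   for window totals (default absolute: compensation magnitude).
#' @return An object of class \code{ridge_trial}; see the methods
#'   vignette for the component list.
#' @export
analyze_trial <- function(top, rear, centroid, meta, cutoff = 0.9,
                          smooth_window = 10, center_n = 500,
                          model = body_model(), response_window = 0.5,
                          stop_threshold = 1,
                          pert_variant = "cylinder_plus_parallel_axis",
                          momentum_mode = "absolute") {
  fps <- top$frame_rate
  top <- apply_likelihood_cutoff(top, cutoff)
  rear <- apply_likelihood_cutoff(rear, cutoff)
  smooth_kp <- function(tb) keypoint_table(
    tb$view, hanning_smooth(tb$x, smooth_window),
    hanning_smooth(tb$y, smooth_window), tb$likelihood, tb$frame_rate)
  top <- smooth_kp(top); rear <- smooth_kp(rear)

  al <- align_on_visibility(top, rear, centroid)
  if (al$top$n_frames < center_n)
    stop("too short: ", al$top$n_frames, " aligned frames < ", center_n)
  top_w <- extract_centered_window(al$top, center_n)
  rear_w <- extract_centered_window(al$rear, center_n)
  cen_w <- extract_centered_window(al$centroid, center_n)
  # original-stream frame index of window sample 1
  frame0 <- al$start_frame + attr(top_w, "window_start") - 1L

  pt <- function(tb, bp) cbind(tb$x[, bp], tb$y[, bp])
  cen_pts <- cbind(
    hanning_smooth(cen_w$x, min(smooth_window, cen_w$n_frames)),
    hanning_smooth(cen_w$y, min(smooth_window, cen_w$n_frames)))

  raw <- list(
    roll_tail = angle_trace("roll_tail",
      roll_tail_angle(pt(rear_w, "tail_base"), pt(rear_w, "tail_mid")),
      fps, "0 = down, 90 = right, 180 = up"),
    yaw_tail = angle_trace("yaw_tail",
      yaw_tail_angle(pt(top_w, "tail_base"), pt(top_w, "tail_mid")),
      fps, "0 = straight back"),
    hip = angle_trace("hip",
      hip_angle(pt(rear_w, "left_hip"), pt(rear_w, "right_hip")),
      fps, "90 = horizontal"),
    back = angle_trace("back",
      back_angle(pt(top_w, "tail_base"), cen_pts), fps,
      "0 = hind body straight back"),
    front = angle_trace("front",
      front_angle(cen_pts, pt(top_w, "nose")), fps,
      "0 = head straight ahead"))
  raw$tail_on_body <- tail_on_body_angle(raw$yaw_tail, raw$back)
  raw$hip_signed <- hip_angle_signed(pt(rear_w, "left_hip"),
                                     pt(rear_w, "right_hip"))

  # tail side from the median roll angle; mirror-normalize to right
  med_roll <- stats::median(raw$roll_tail$values) %% 360
  tail_side <- if (med_roll < 180) "right" else "left"
  canon <- if (tail_side == "left") mirror_angle_traces(raw) else raw

  # step events on the contralateral (opposite the tail side) hind paw:
  # forward paw excursion relative to the tail base
  contra <- if (tail_side == "right") "left_hind_paw" else "right_hind_paw"
  paw_rel <- top_w$x[, contra] - top_w$x[, "tail_base"]
  expected_period <- fps / 4  # 4 Hz nominal stride
  events <- suppressWarnings(
    detect_step_peaks(paw_rel, min_separation = round(expected_period / 2)))
  halfwidth <- if (!is.na(events$stride_period_frames))
    round(events$stride_period_frames) else round(expected_period)
  # mean-interval frequency estimate: averages out the frame quantization
  # of individual peak positions
  ev <- events$event_frames
  stride_freq <- if (length(ev) >= 2)
    fps * (length(ev) - 1) / (ev[length(ev)] - ev[1]) else NA_real_

  # angular velocities (deg/s) and momentum traces
  omega_tail <- angular_velocity(canon$roll_tail)
  omega_body <- angular_velocity(canon$hip_signed, frame_rate = fps)
  l_tail <- tail_momentum(deg2rad_s(omega_tail), model, fps)
  l_body <- body_momentum(deg2rad_s(omega_body), model, fps)
  l_sum <- sum_momentum(l_tail, l_body)

  balance <- balance_report(cen_w, meta, stop_threshold = stop_threshold)

  tilt_res <- NULL
  if (meta$tilt_present) {
    onset_w <- meta$tilt$onset - frame0 + 1L
    if (onset_w >= 1 && onset_w + round(response_window * fps) <= center_n) {
      lat <- tryCatch(
        classify_laterality(raw$roll_tail$values[onset_w],
                            meta$tilt$direction),
        error = function(e) NULL)
      tilt_w <- tilt_profile(meta$tilt$amplitude, meta$tilt$duration,
                             meta$tilt$direction, onset_w)
      l_pert <- perturbation_momentum(tilt_w, model, center_n, fps,
                                      variant = pert_variant)
      win <- c((onset_w - 1) / fps, (onset_w - 1) / fps + response_window)
      tot <- vapply(list(tail = l_tail, body = l_body, sum = l_sum,
                         pert = l_pert),
                    integrate_momentum, numeric(1),
                    window = win, mode = momentum_mode)
      rel <- relative_momentum(tot[["tail"]], tot[["body"]], tot[["pert"]])
      # response kinematics within the post-onset window
      resp <- onset_w:(onset_w + round(response_window * fps))
      # times to peak are read from re-smoothed angle traces: the raw
      # argmax wanders on the flat top of the response when the
      # deflection is small relative to the residual pixel noise
      u_roll <- hanning_smooth(unwrap_deg(canon$roll_tail$values),
                               smooth_window)
      disp <- u_roll[resp] - u_roll[onset_w]
      pk <- which.max(abs(disp))
      # peak angular speed from a short median-filtered velocity trace:
      # suppresses residual pixel-noise spikes without attenuating the
      # smooth swing peak
      om_med <- stats::runmed(omega_tail, 7)
      swing_speed_rps <- max(abs(om_med[resp])) / 360
      u_hip <- hanning_smooth(canon$hip_signed, smooth_window)
      hdisp <- u_hip[resp] - u_hip[onset_w]
      tilt_res <- list(
        laterality = if (is.null(lat)) NA_character_ else lat$label,
        onset_window_frame = onset_w,
        perturbation = l_pert,
        totals = tot, relative = rel,
        phases = list(
          tail = split_phases(l_tail, tilt_w, response_window,
                              momentum_mode),
          body = split_phases(l_body, tilt_w, response_window,
                              momentum_mode),
          sum = split_phases(l_sum, tilt_w, response_window,
                             momentum_mode)),
        swing_peak_speed_rps = swing_speed_rps,
        tail_time_to_peak_s = (pk - 1) / fps,
        body_time_to_peak_s = (which.max(abs(hdisp)) - 1) / fps)
    }
  }

  structure(list(
    meta = meta, frame0 = frame0, frame_rate = fps,
    tail_side = tail_side, stride_frequency_hz = stride_freq,
    angles_raw = raw, angles = canon,
    omega_tail = omega_tail, omega_body = omega_body,
    momentum = list(tail = l_tail, body = l_body, sum = l_sum),
    events = events, halfwidth = halfwidth,
    balance = balance, tilt = tilt_res,
    windowed = list(top = top_w, rear = rear_w, centroid = cen_w)),
    class = "ridge_trial")
}

#' @export
print.ridge_trial <- function(x, ...) {
  cat("Ridge trial — animal ", x$meta$animal_id,
      ", width ", x$meta$ridge_width, " mm, tail held ", x$tail_side,
      "\n", sep = "")
  cat("  ", length(x$events$event_frames), " step events",
      if (!is.na(x$events$stride_period_frames))
        paste0(" (stride ", round(x$events$stride_period_frames),
               " frames)"), "\n", sep = "")
  cat("  traversing speed ", round(x$balance$traversing_speed, 1),
      " mm/s, centrality ", round(x$balance$centrality, 3), "\n", sep = "")
  if (!is.null(x$tilt))
    cat("  tilt: ", x$tilt$laterality, ", swing peak ",
        round(x$tilt$swing_peak_speed_rps, 2), " rot/s, relative momentum (sum) ",
        round(x$tilt$relative["sum"], 3), "\n", sep = "")
  invisible(x)
}

#' @export
summary.ridge_trial <- function(object, ...) {
  x <- object
  out <- data.frame(
    animal_id = x$meta$animal_id,
    trial_id = if (is.null(x$meta$trial_id)) NA_character_
               else x$meta$trial_id,
    ridge_width = x$meta$ridge_width,
    tail_side = x$tail_side,
    n_steps = length(x$events$event_frames),
    stride_period_frames = x$events$stride_period_frames,
    stride_frequency_hz = x$stride_frequency_hz,
    traversing_speed = x$balance$traversing_speed,
    time_outside_bos_s = x$balance$time_outside_bos_s,
    lateral_movement_mm = x$balance$lateral_movement_mm,
    centrality = x$balance$centrality,
    laterality = if (is.null(x$tilt)) NA_character_ else x$tilt$laterality,
    swing_peak_speed_rps = if (is.null(x$tilt)) NA_real_
                           else x$tilt$swing_peak_speed_rps,
    tail_time_to_peak_s = if (is.null(x$tilt)) NA_real_
                          else x$tilt$tail_time_to_peak_s,
    body_time_to_peak_s = if (is.null(x$tilt)) NA_real_
                          else x$tilt$body_time_to_peak_s,
    rel_momentum_tail = if (is.null(x$tilt)) NA_real_
                        else x$tilt$relative["tail"],
    rel_momentum_body = if (is.null(x$tilt)) NA_real_
                        else x$tilt$relative["body"],
    rel_momentum_sum = if (is.null(x$tilt)) NA_real_
                       else x$tilt$relative["sum"])
  rownames(out) <- NULL
  out
}

#' Plot a ridge trial
#'
#' Two-panel base-graphics figure: the roll-plane tail and hip angle
#' traces (with step events and tilt onset marked), and the momentum
#' traces.
#'
#' @param x A \code{ridge_trial}.
#' @param ... Ignored.
#' @export
plot.ridge_trial <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  t <- (seq_along(x$angles$roll_tail$values) - 1) / x$frame_rate
  graphics::plot(t, x$angles$roll_tail$values, type = "l", col = "firebrick",
                 xlab = "time (s)", ylab = "angle (deg)",
                 main = "Tail roll (red) and signed hip (green) angles")
  graphics::lines(t, x$angles$hip_signed, col = "forestgreen")
  graphics::abline(v = (x$events$event_frames - 1) / x$frame_rate,
                   col = grDevices::adjustcolor("grey40", 0.4), lty = 3)
  if (!is.null(x$tilt))
    graphics::abline(v = (x$tilt$onset_window_frame - 1) / x$frame_rate,
                     col = "blue", lty = 2)
  graphics::plot(t, x$momentum$tail$values, type = "l", col = "firebrick",
                 xlab = "time (s)", ylab = "L (kg m^2/s)",
                 main = "Momentum: tail (red), body (green), sum (black)")
  graphics::lines(t, x$momentum$body$values, col = "forestgreen")
  graphics::lines(t, x$momentum$sum$values, col = "black")
  invisible(x)
}

log_line <- function(con, ...) {
  writeLines(jsonlite::toJSON(list(...), auto_unbox = TRUE), con)
}

#' Run the analysis over a simulated or recorded cohort
#'
#' Reads a YAML manifest (as written by \code{\link{simulate_cohort}}),
#' analyzes every trial, and aggregates per-trial metrics, momentum
#' totals, step-cycle statistics, per-width tail-body momentum
#' cross-correlograms and group statistics. Per-trial failures are
#' logged and recorded in an exclusions table, never silently dropped.
#'
#' @param manifest_path Path to the manifest YAML.
#' @param out_dir Output directory for tidy CSV tables and the JSON-lines
#'   run log (\code{NULL}: nothing written).
#' @param cutoff,smooth_window,center_n,response_window,stop_threshold,
#'   pert_variant,momentum_mode,model As in \code{\link{analyze_trial}}.
#' @param correlogram_pct Percentile for hotspot/coldspot detection.
#' @return A results bundle (list of data.frames and correlograms) of
#'   class \code{ridge_results}.
#' @export
run_analyze <- function(manifest_path, out_dir = NULL, cutoff = 0.9,
                        smooth_window = 10, center_n = 500,
                        response_window = 0.5, stop_threshold = 1,
                        pert_variant = "cylinder_plus_parallel_axis",
                        momentum_mode = "absolute", model = body_model(),
                        correlogram_pct = 5) {
  manifest <- yaml::read_yaml(manifest_path)
  base <- dirname(manifest_path)
  fps <- if (!is.null(manifest$frame_rate)) manifest$frame_rate else 300
  logcon <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    logcon <- file(file.path(out_dir, "run_log.jsonl"), "w")
    on.exit(close(logcon))
    log_line(logcon, event = "config", cutoff = cutoff,
             smooth_window = smooth_window, center_n = center_n,
             response_window = response_window,
             stop_threshold = stop_threshold, pert_variant = pert_variant,
             momentum_mode = momentum_mode,
             correlogram_pct = correlogram_pct,
             model = unclass(model))
  }
  trial_rows <- list(); cycle_rows <- list(); excl <- list()
  epochs_tail <- list(); epochs_body <- list()
  for (tr in manifest$trials) {
    res <- tryCatch({
      top <- read_keypoint_table(file.path(base, tr$top), "top", fps)
      rear <- read_keypoint_table(file.path(base, tr$rear), "rear", fps)
      cen <- read_centroid_csv(file.path(base, tr$centroid), fps)
      tilt <- if (isTRUE(tr$tilt_present))
        tilt_profile(tr$tilt_amplitude, tr$tilt_duration,
                     tr$tilt_direction, tr$tilt_onset) else NULL
      meta <- trial_meta(tr$animal_id, tr$ridge_width, tilt = tilt,
                         mm_per_pixel = c(top = manifest$mm_per_pixel,
                                          rear = manifest$mm_per_pixel),
                         trial_id = tr$trial_id)
      a <- analyze_trial(top, rear, cen, meta, cutoff = cutoff,
                         smooth_window = smooth_window,
                         center_n = center_n, model = model,
                         response_window = response_window,
                         stop_threshold = stop_threshold,
                         pert_variant = pert_variant,
                         momentum_mode = momentum_mode)
      a
    }, error = function(e) e)
    if (inherits(res, "error")) {
      reason <- conditionMessage(res)
      excl[[length(excl) + 1]] <- data.frame(
        trial_id = tr$trial_id, reason = reason)
      if (!is.null(logcon))
        log_line(logcon, event = "excluded", trial = tr$trial_id,
                 reason = reason)
      next
    }
    row <- summary(res)
    row$slip_count <- if (!is.null(tr$slip_count)) tr$slip_count else NA
    trial_rows[[length(trial_rows) + 1]] <- row
    if (length(res$events$event_frames) >= 1) {
      cyc_roll <- align_epochs(res$angles$roll_tail$values, res$events,
                               res$halfwidth, fps)
      cyc_hip <- align_epochs(res$angles$hip_signed, res$events,
                              res$halfwidth, fps)
      if (cyc_roll$n_epochs >= 1) {
        cs_r <- cycle_stats(cyc_roll); cs_h <- cycle_stats(cyc_hip)
        cycle_rows[[length(cycle_rows) + 1]] <- data.frame(
          trial_id = tr$trial_id, animal_id = tr$animal_id,
          ridge_width = tr$ridge_width,
          tail_mean_position = cs_r$trial["mean_position"],
          tail_range = cs_r$trial["range"],
          hip_mean_position = cs_h$trial["mean_position"],
          hip_range = cs_h$trial["range"], row.names = NULL)
      }
      # momentum epochs for the coupling analysis, pooled per width over
      # non-perturbation trials (tilt responses are not step-locked and
      # would swamp the locomotor coupling)
      mt <- align_epochs(res$momentum$tail$values, res$events,
                         res$halfwidth, fps)
      mb <- align_epochs(res$momentum$body$values, res$events,
                         res$halfwidth, fps)
      if (mt$n_epochs >= 1 && !isTRUE(tr$tilt_present)) {
        key <- as.character(tr$ridge_width)
        # fixed epoch length across trials: resample to a common grid
        epochs_tail[[key]] <- c(epochs_tail[[key]], list(mt))
        epochs_body[[key]] <- c(epochs_body[[key]], list(mb))
      }
    }
    if (!is.null(logcon))
      log_line(logcon, event = "analyzed", trial = tr$trial_id,
               n_steps = length(res$events$event_frames),
               laterality = if (is.null(res$tilt)) NA
                            else res$tilt$laterality)
  }
  trials_df <- do.call(rbind, trial_rows)
  cycles_df <- if (length(cycle_rows)) do.call(rbind, cycle_rows) else NULL
  excl_df <- if (length(excl)) do.call(rbind, excl)
             else data.frame(trial_id = character(0), reason = character(0))

  # per-width correlograms on a common epoch grid
  correlograms <- list()
  for (key in names(epochs_tail)) {
    hw <- min(vapply(epochs_tail[[key]], function(e) e$halfwidth,
                     numeric(1)))
    crop <- function(sets) do.call(rbind, lapply(sets, function(s) {
      mid <- s$halfwidth + 1
      s$epochs[, (mid - hw):(mid + hw), drop = FALSE]
    }))
    te <- crop(epochs_tail[[key]]); be <- crop(epochs_body[[key]])
    if (nrow(te) >= 3) {
      cc <- build_correlogram(te, be)
      cc$bin_times <- (-hw:hw) / fps
      cc$regions <- find_extreme_regions(cc, correlogram_pct)
      correlograms[[key]] <- cc
    }
  }

  # group statistics: per-animal means across widths
  stats_tables <- NULL
  if (!is.null(trials_df) && length(unique(trials_df$ridge_width)) >= 2) {
    per_animal <- stats::aggregate(
      trials_df[c("traversing_speed", "lateral_movement_mm", "centrality",
                  "time_outside_bos_s")],
      by = list(animal_id = trials_df$animal_id,
                ridge_width = trials_df$ridge_width),
      FUN = mean, na.rm = TRUE)
    mk <- function(metric) group_comparison(
      split(per_animal[[metric]], per_animal$ridge_width), metric = metric)
    gc_list <- lapply(c("traversing_speed", "lateral_movement_mm",
                        "centrality", "time_outside_bos_s"), mk)
    stats_tables <- list(
      anova = do.call(rbind, lapply(gc_list, `[[`, "anova")),
      posthoc = do.call(rbind, lapply(gc_list, `[[`, "posthoc")),
      summary = do.call(rbind, lapply(gc_list, `[[`, "summary")))
  }

  bundle <- structure(list(
    trials = trials_df, cycles = cycles_df, exclusions = excl_df,
    correlograms = correlograms, stats = stats_tables,
    params = list(cutoff = cutoff, smooth_window = smooth_window,
                  center_n = center_n, response_window = response_window,
                  stop_threshold = stop_threshold,
                  pert_variant = pert_variant,
                  momentum_mode = momentum_mode,
                  correlogram_pct = correlogram_pct)),
    class = "ridge_results")
  if (!is.null(out_dir)) {
    utils::write.csv(trials_df, file.path(out_dir, "trials.csv"),
                     row.names = FALSE)
    if (!is.null(cycles_df))
      utils::write.csv(cycles_df, file.path(out_dir, "cycle_stats.csv"),
                       row.names = FALSE)
    utils::write.csv(excl_df, file.path(out_dir, "exclusions.csv"),
                     row.names = FALSE)
    for (key in names(correlograms))
      utils::write.csv(correlograms[[key]]$matrix,
                       file.path(out_dir, paste0("correlogram_w", key,
                                                 ".csv")),
                       row.names = FALSE)
    if (!is.null(stats_tables)) {
      utils::write.csv(stats_tables$anova,
                       file.path(out_dir, "stats_anova.csv"),
                       row.names = FALSE)
      utils::write.csv(stats_tables$posthoc,
                       file.path(out_dir, "stats_posthoc.csv"),
                       row.names = FALSE)
    }
    if (!is.null(logcon))
      log_line(logcon, event = "done",
               n_trials = if (is.null(trials_df)) 0 else nrow(trials_df),
               n_excluded = nrow(excl_df))
  }
  bundle
}

#' @export
print.ridge_results <- function(x, ...) {
  cat("Ridge-cohort results:",
      if (is.null(x$trials)) 0 else nrow(x$trials), "trials analyzed,",
      nrow(x$exclusions), "excluded\n")
  if (!is.null(x$trials)) {
    tw <- table(x$trials$ridge_width)
    cat("  widths:", paste(names(tw), "mm (", tw, ")", collapse = ", "),
        "\n")
    sp <- mean_sem(x$trials$swing_peak_speed_rps)
    if (sp["n"] > 0)
      cat("  tilt-evoked swing speed:", round(sp["mean"], 2), "+/-",
          round(sp["sem"], 3), "rot/s (n =", sp["n"], "tilt trials)\n")
  }
  invisible(x)
}

#' Write summary tables and figures for a results bundle
#'
#' Emits tidy CSV width-by-metric summaries and vector (PDF) figures:
#' width-vs-metric summary panels, tilt-response momentum summaries and
#' per-width correlogram heatmaps.
#'
#' @param bundle A \code{ridge_results} from \code{\link{run_analyze}}.
#' @param out_dir Output directory.
#' @return Invisibly, the paths written.
#' @export
run_report <- function(bundle, out_dir) {
  stopifnot(inherits(bundle, "ridge_results"))
  if (is.null(bundle$trials) || nrow(bundle$trials) == 0)
    stop("report error: empty results bundle")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)

  widths <- sort(unique(bundle$trials$ridge_width))
  metrics <- c("traversing_speed", "lateral_movement_mm", "centrality",
               "time_outside_bos_s", "swing_peak_speed_rps",
               "rel_momentum_sum")
  summ <- do.call(rbind, lapply(widths, function(w) {
    sub <- bundle$trials[bundle$trials$ridge_width == w, ]
    row <- data.frame(ridge_width = w, n_trials = nrow(sub))
    for (m in metrics) {
      ms <- mean_sem(sub[[m]])
      row[[paste0(m, "_mean")]] <- ms["mean"]
      row[[paste0(m, "_sem")]] <- ms["sem"]
    }
    row
  }))
  p <- file.path(out_dir, "width_summary.csv")
  utils::write.csv(summ, p, row.names = FALSE)
  paths <- c(paths, p)

  p <- file.path(out_dir, "fig_width_vs_metrics.pdf")
  grDevices::pdf(p, width = 9, height = 6)
  op <- graphics::par(mfrow = c(2, 3), mar = c(4, 4, 2, 1))
  for (m in metrics) {
    mu <- summ[[paste0(m, "_mean")]]; se <- summ[[paste0(m, "_sem")]]
    if (all(!is.finite(mu))) next
    ylim <- range(c(mu - se, mu + se, 0), na.rm = TRUE)
    graphics::plot(summ$ridge_width, mu, type = "b", pch = 19,
                   ylim = ylim, xlab = "ridge width (mm)", ylab = m,
                   main = m)
    ok <- is.finite(se) & se > 0
    if (any(ok))
      graphics::arrows(summ$ridge_width[ok], (mu - se)[ok],
                       summ$ridge_width[ok], (mu + se)[ok],
                       angle = 90, code = 3, length = 0.03)
  }
  graphics::par(op)
  grDevices::dev.off()
  paths <- c(paths, p)

  if (length(bundle$correlograms)) {
    p <- file.path(out_dir, "fig_correlograms.pdf")
    grDevices::pdf(p, width = 4 * length(bundle$correlograms), height = 4)
    op <- graphics::par(mfrow = c(1, length(bundle$correlograms)),
                        mar = c(4, 4, 2, 1))
    for (key in names(bundle$correlograms)) {
      cc <- bundle$correlograms[[key]]
      graphics::image(cc$bin_times, cc$bin_times, cc$matrix,
                      col = grDevices::hcl.colors(64, "RdBu", rev = TRUE),
                      zlim = c(-1, 1) * max(abs(cc$matrix), na.rm = TRUE),
                      xlab = "tail bin (s)", ylab = "body bin (s)",
                      main = paste0("width ", key, " mm (n=", cc$n_trials,
                                    ")"))
    }
    graphics::par(op)
    grDevices::dev.off()
    paths <- c(paths, p)
  }

  if (!is.null(bundle$stats)) {
    p <- file.path(out_dir, "stats_summary.csv")
    utils::write.csv(bundle$stats$summary, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
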