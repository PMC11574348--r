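# Step-cycle segmentation and step-aligned epoching.
#
# A step cycle is anchored on the peak of the forward (x-projection)
# excursion of the hind paw contralateral to the side on which the tail is
# held; angle and momentum traces are epoched around those events.

#' Detect step events as forward-excursion peaks
#'
#' Finds local maxima of the (smoothed) paw x-projection subject to a
#' minimum separation and a minimum topographic prominence; peaks are
#' accepted greedily in order of decreasing height.
#'
#' @param paw_x Numeric time series (smoothed paw forward coordinate).
#' @param min_separation Minimum frames between accepted peaks
#'   (default: half the expected 4 Hz stride period at 300 fps).
#' @param min_prominence Minimum prominence; default 25\% of the series'
#'   interquartile range.
#' @return An object of class \code{step_events}: list with \code{event_frames}
#'   (ordered indices), \code{stride_period_frames} (median inter-event
#'   interval, \code{NA} if fewer than 2 events) and the parameters used.
#'   Zero detected peaks yields an empty series with a warning.
#' @export
detect_step_peaks <- function(paw_x,
                              min_separation = 38,
                              min_prominence = 0.25 * stats::IQR(paw_x)) {
  stopifnot(min_separation >= 1)
  n <- length(paw_x)
  # local maxima (plateaus: first sample of the plateau)
  cand <- which(diff(sign(diff(paw_x))) < 0) + 1L
  cand <- cand[paw_x[cand] > paw_x[pmax(cand - 1L, 1L)] |
               paw_x[cand] > paw_x[pmin(cand + 1L, n)]]
  if (length(cand)) {
    prom <- vapply(cand, function(i) peak_prominence(paw_x, i), numeric(1))
    cand <- cand[prom >= min_prominence]
  }
  keep <- integer(0)
  if (length(cand)) {
    for (i in cand[order(paw_x[cand], decreasing = TRUE)]) {
      if (all(abs(keep - i) >= min_separation)) keep <- c(keep, i)
    }
    keep <- sort(keep)
  }
  if (!length(keep))
    warning("no step peaks found; trial will be excluded from cycle analyses")
  structure(list(
    event_frames = keep,
    stride_period_frames = if (length(keep) >= 2)
      stats::median(diff(keep)) else NA_real_,
    min_separation = min_separation, min_prominence = min_prominence),
    class = "step_events")
}

# topographic prominence of a local maximum: height above the higher of the
# two key saddles (minima between the peak and the nearest higher terrain,
# or the series end)
peak_prominence <- function(x, i) {
  n <- length(x); h <- x[i]
  left <- if (i > 1) {
    higher <- which(x[1:(i - 1)] > h)
    lo <- if (length(higher)) (max(higher) + 1L) else 1L
    min(x[lo:(i - 1)])
  } else h
  right <- if (i < n) {
    higher <- which(x[(i + 1):n] > h)
    hi <- if (length(higher)) (i + min(higher) - 1L) else n
    min(x[(i + 1):hi])
  } else h
  h - max(left, right)
}

#' @export
print.step_events <- function(x, ...) {
  cat("Step events:", length(x$event_frames), "peaks")
  if (!is.na(x$stride_period_frames))
    cat(", median stride period", x$stride_period_frames, "frames")
  cat("\n")
  invisible(x)
}

#' Epoch a trace around step events
#'
#' Cuts fixed-length windows (event frame +/- halfwidth) out of a trace,
#' one per step event; epochs that would overrun either trial edge are
#' excluded.
#'
#' @param trace Numeric time series.
#' @param events A \code{step_events} object (or vector of event frames).
#' @param halfwidth Half window length in frames (>= 1). The conventional
#'   default is one median stride period, giving two-cycle windows.
#' @param frame_rate Frames per second, used for the epoch time axis.
#' @return An object of class \code{step_cycles}: list with \code{epochs}
#'   (matrix, one row per epoch), \code{event_frames} of the retained
#'   epochs, \code{halfwidth}, \code{n_epochs} and \code{bin_times}
#'   (seconds relative to the event).
#' @export
align_epochs <- function(trace, events, halfwidth, frame_rate = 300) {
  ev <- if (inherits(events, "step_events")) events$event_frames else events
  stopifnot(halfwidth >= 1)
  n <- length(trace)
  ok <- ev[ev - halfwidth >= 1 & ev + halfwidth <= n]
  if (!length(ok)) {
    warning("all epochs clipped at trial edges; empty step-cycle set")
    epochs <- matrix(numeric(0), 0, 2 * halfwidth + 1)
  } else {
    epochs <- t(vapply(ok, function(e) trace[(e - halfwidth):(e + halfwidth)],
                       numeric(2 * halfwidth + 1)))
  }
  structure(list(epochs = epochs, event_frames = ok,
                 halfwidth = halfwidth, n_epochs = nrow(epochs),
                 bin_times = (-halfwidth:halfwidth) / frame_rate),
            class = "step_cycles")
}

#' @export
print.step_cycles <- function(x, ...) {
  cat("Step-cycle set:", x$n_epochs, "epochs of",
      2 * x$halfwidth + 1, "frames\n")
  invisible(x)
}

#' Per-cycle summary statistics
#'
#' For each epoch: the mean of the trace (mean position through the step
#' cycle) and its range (max - min); plus their per-trial averages over
#' epochs.
#'
#' @param cycles A \code{step_cycles} object with at least one epoch.
#' @return List with \code{per_epoch} (data.frame: epoch, mean, range) and
#'   \code{trial} (named vector: mean_position, range).
#' @export
cycle_stats <- function(cycles) {
  stopifnot(inherits(cycles, "step_cycles"))
  if (cycles$n_epochs < 1)
    stop("empty step-cycle set: cycle statistics undefined")
  m <- rowMeans(cycles$epochs)
  r <- apply(cycles$epochs, 1, function(e) max(e) - min(e))
  list(per_epoch = data.frame(epoch = seq_len(cycles$n_epochs),
                              mean = m, range = r),
       trial = c(mean_position = mean(m), range = mean(r)))
}
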