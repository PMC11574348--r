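# Keypoint-table I/O and trace conditioning.
#
# Coordinate conventions used throughout the package:
#  * rear view: x = lateral (pixels, animal's right is +x), y = vertical, up is +y
#  * top view:  x = forward along the ridge axis, y = lateral
# Raw tracker tables use image coordinates (y down); `read_keypoint_table()`
# flips y at the I/O boundary so all downstream angle math assumes y up.

#' Construct a keypoint table
#'
#' A keypoint table holds per-frame (x, y, likelihood) triplets for a set of
#' named bodyparts tracked in one camera view, in math coordinates (y up).
#'
#' @param view Camera view, \code{"rear"} or \code{"top"}.
#' @param x,y,likelihood Numeric matrices, frames in rows, one column per
#'   bodypart (column names are the bodypart names). \code{NA} marks a
#'   missing sample.
#' @param frame_rate Frames per second (default 300).
#' @return An object of class \code{keypoint_table}.
#' @export
keypoint_table <- function(view, x, y, likelihood, frame_rate = 300) {
  view <- match.arg(view, c("rear", "top"))
  x <- as.matrix(x); y <- as.matrix(y); likelihood <- as.matrix(likelihood)
  if (!identical(dim(x), dim(y)) || !identical(dim(x), dim(likelihood)))
    stop("integrity error: x, y and likelihood must share dimensions ",
         "(mixed frame counts)")
  if (is.null(colnames(x))) colnames(x) <- paste0("bp", seq_len(ncol(x)))
  colnames(y) <- colnames(likelihood) <- colnames(x)
  if (!is.numeric(frame_rate) || length(frame_rate) != 1 || frame_rate <= 0)
    stop("frame_rate must be a positive scalar")
  bad <- likelihood < 0 | likelihood > 1
  if (any(bad, na.rm = TRUE))
    stop("integrity error: likelihood outside [0, 1] (first offending value ",
         format(likelihood[which(bad)[1]]), ")")
  structure(
    list(view = view, frame_rate = frame_rate, bodyparts = colnames(x),
         n_frames = nrow(x), x = x, y = y, likelihood = likelihood),
    class = "keypoint_table")
}

#' @export
print.keypoint_table <- function(x, ...) {
  cat("Keypoint table (", x$view, " view): ", x$n_frames, " frames @ ",
      x$frame_rate, " fps\n", sep = "")
  cat("  bodyparts:", paste(x$bodyparts, collapse = ", "), "\n")
  nmiss <- sum(is.na(x$x))
  if (nmiss > 0) cat("  missing samples:", nmiss, "\n")
  invisible(x)
}

#' Read a keypoint table from a 3-row-header CSV
#'
#' Parses the multi-row-header CSV dialect emitted by common markerless
#' trackers (DeepLabCut-style): header rows \code{scorer}, \code{bodyparts},
#' \code{coords}, then one row per frame with an index column followed by
#' (x, y, likelihood) triplets per bodypart. Image-coordinate y (down) is
#' converted to math-coordinate y (up) by negation.
#'
#' @param path Path to the CSV file.
#' @param view Camera view the table was recorded from.
#' @param frame_rate Frames per second (default 300).
#' @return A \code{\link{keypoint_table}}. Missing cells stay \code{NA}.
#' @export
read_keypoint_table <- function(path, view, frame_rate = 300) {
  if (!file.exists(path)) stop("file not found: ", path)
  hdr <- readLines(path, n = 3L)
  if (length(hdr) < 3L)
    stop("format error: expected a 3-row header (scorer/bodyparts/coords), ",
         "file has ", length(hdr), " line(s)")
  split_row <- function(s) {
    out <- scan(text = s, what = character(), sep = ",", quiet = TRUE,
                strip.white = TRUE)
    out
  }
  rows <- lapply(hdr, split_row)
  labs <- vapply(rows, function(r) tolower(r[1]), character(1))
  if (!identical(labs[2], "bodyparts"))
    stop("format error in header row 2: expected label 'bodyparts', got '",
         rows[[2]][1], "'")
  if (!identical(labs[3], "coords"))
    stop("format error in header row 3: expected label 'coords', got '",
         rows[[3]][1], "'")
  bps <- rows[[2]][-1]
  coords <- tolower(rows[[3]][-1])
  if (length(bps) != length(coords) || length(bps) %% 3L != 0L)
    stop("format error in header row 3: expected x,y,likelihood triplets")
  ord <- rep(c("x", "y", "likelihood"), length(bps) / 3L)
  if (!identical(coords, ord))
    stop("format error in header row 3: coords must cycle x,y,likelihood")
  ubp <- bps[seq(1, length(bps), by = 3)]
  if (!all(bps == rep(ubp, each = 3)))
    stop("format error in header row 2: bodypart names not in triplets")

  dat <- utils::read.csv(path, skip = 3, header = FALSE,
                         colClasses = "numeric")
  if (ncol(dat) != length(bps) + 1L)
    stop("integrity error: data rows have ", ncol(dat) - 1L,
         " value columns, header declares ", length(bps))
  m <- as.matrix(dat[, -1, drop = FALSE])
  idx <- function(k) seq(k, ncol(m), by = 3)
  x <- m[, idx(1), drop = FALSE]
  y <- -m[, idx(2), drop = FALSE]   # image y-down -> math y-up
  l <- m[, idx(3), drop = FALSE]
  colnames(x) <- ubp
  keypoint_table(view, x, y, l, frame_rate)
}

#' Write a keypoint table to the 3-row-header CSV dialect
#'
#' Inverse of \code{\link{read_keypoint_table}}: math-coordinate y is
#' converted back to image coordinates, so write-then-read round-trips to
#' full precision.
#'
#' @param table A \code{keypoint_table}.
#' @param path Output CSV path.
#' @param scorer Scorer label for header row 1.
#' @return \code{path}, invisibly.
#' @export
write_keypoint_table <- function(table, path, scorer = "tailbalance") {
  stopifnot(inherits(table, "keypoint_table"))
  p <- length(table$bodyparts)
  h1 <- paste(c("scorer", rep(scorer, 3 * p)), collapse = ",")
  h2 <- paste(c("bodyparts", rep(table$bodyparts, each = 3)), collapse = ",")
  h3 <- paste(c("coords", rep(c("x", "y", "likelihood"), p)), collapse = ",")
  m <- matrix(NA_real_, table$n_frames, 3 * p)
  m[, seq(1, 3 * p, by = 3)] <- table$x
  m[, seq(2, 3 * p, by = 3)] <- -table$y
  m[, seq(3, 3 * p, by = 3)] <- table$likelihood
  body <- cbind(seq_len(table$n_frames) - 1L, m)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(h1, h2, h3), con)
  utils::write.table(format(body, digits = 17, trim = TRUE, scientific = FALSE),
                     con, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Condition coordinates on tracking likelihood
#'
#' Samples whose likelihood falls below \code{cutoff} are invalidated and
#' replaced by linear interpolation between the nearest valid neighbours
#' (gaps at the edges are filled by nearest-valid extension), so downstream
#' gradients stay defined. The per-bodypart count of replaced samples is
#' attached as attribute \code{"n_replaced"}.
#'
#' @param table A \code{keypoint_table}.
#' @param cutoff Likelihood threshold in [0, 1]; the tracker's conventional
#'   default is 0.9.
#' @return A conditioned \code{keypoint_table}. Idempotent at fixed cutoff.
#' @export
apply_likelihood_cutoff <- function(table, cutoff = 0.9) {
  stopifnot(inherits(table, "keypoint_table"))
  if (!is.numeric(cutoff) || cutoff < 0 || cutoff > 1)
    stop("cutoff must lie in [0, 1]")
  x <- table$x; y <- table$y; lik <- table$likelihood
  n_replaced <- integer(length(table$bodyparts))
  names(n_replaced) <- table$bodyparts
  for (j in seq_along(table$bodyparts)) {
    bad <- is.na(lik[, j]) | lik[, j] < cutoff | is.na(x[, j]) | is.na(y[, j])
    if (all(bad))
      stop("unusable bodypart '", table$bodyparts[j],
           "': no sample at or above the likelihood cutoff")
    if (any(bad)) {
      ok <- which(!bad)
      x[, j] <- stats::approx(ok, x[ok, j], xout = seq_len(nrow(x)),
                              rule = 2)$y
      y[, j] <- stats::approx(ok, y[ok, j], xout = seq_len(nrow(y)),
                              rule = 2)$y
      lik[bad, j] <- 1  # replaced samples are now trusted values
      n_replaced[j] <- sum(bad)
    }
  }
  out <- keypoint_table(table$view, x, y, lik, table$frame_rate)
  attr(out, "n_replaced") <- n_replaced
  out
}

# Normalized symmetric Hanning kernel without zero endpoints
# (w_k = 0.5 * (1 - cos(2*pi*k / (M+1))), k = 1..M), so every stated
# window length contributes M nonzero taps; M = 1 is the identity.
hanning_kernel <- function(window) {
  k <- seq_len(window)
  w <- 0.5 * (1 - cos(2 * pi * k / (window + 1)))
  w / sum(w)
}

#' Hanning-smooth a time series
#'
#' Moving-average filtering with a raised-cosine (Hanning) kernel of the
#' given length, weights normalized to unit sum. Edges are reflect-padded so
#' the output has the input's length and constant series pass unchanged.
#' The conventional smoothing for 300 fps kinematic traces is a 10-frame
#' (33 ms) window.
#'
#' @param series Numeric vector (or matrix with frames in rows; columns are
#'   smoothed independently).
#' @param window Kernel length in frames (default 10); \code{window = 1} is
#'   the identity.
#' @return Smoothed series of the same shape.
#' @export
hanning_smooth <- function(series, window = 10) {
  if (is.matrix(series))
    return(apply(series, 2, hanning_smooth, window = window))
  if (!is.numeric(window) || length(window) != 1 || window < 1 ||
      window != round(window))
    stop("window must be a positive integer number of frames")
  n <- length(series)
  if (window > n) stop("window (", window, ") exceeds series length (", n, ")")
  if (window == 1) return(series)
  w <- hanning_kernel(window)
  if (window %% 2 == 0) {
    # an even-length kernel cannot be centred on a sample; averaging its two
    # half-sample placements gives a zero-phase (odd, length M+1) kernel and
    # keeps linear trends unshifted
    w <- (c(w, 0) + c(0, w)) / 2
    window <- window + 1L
  }
  pad <- min(window, n - 1L)  # reflect padding (edge sample not repeated)
  left <- if (pad > 0) series[(pad + 1):2] else numeric(0)
  right <- if (pad > 0) series[(n - 1):(n - pad)] else numeric(0)
  ext <- c(left, series, right)
  half_l <- (window - 1L) %/% 2L  # taps to the left of the kernel centre
  conv <- stats::convolve(ext, rev(w), type = "open")
  off <- length(left)
  core <- conv[(off - half_l + window):(off - half_l + window + n - 1L)]
  as.numeric(core)
}

#' Construct a centroid trace
#'
#' Per-frame top-view body-silhouette centroid with a visibility flag; the
#' silhouette centroid approximates the animal's centre of mass (CoM).
#'
#' @param x,y Numeric vectors: forward and lateral centroid coordinates
#'   (pixels unless stated otherwise).
#' @param visible Logical vector (default: visible wherever x is finite).
#' @param frame_rate Frames per second.
#' @return An object of class \code{centroid_trace}.
#' @export
centroid_trace <- function(x, y, visible = is.finite(x) & is.finite(y),
                           frame_rate = 300) {
  stopifnot(length(x) == length(y), length(visible) == length(x))
  structure(list(x = as.numeric(x), y = as.numeric(y),
                 visible = as.logical(visible),
                 n_frames = length(x), frame_rate = frame_rate),
            class = "centroid_trace")
}

#' Centroid of a binary silhouette mask
#'
#' @param mask Logical or 0/1 matrix; \code{TRUE}/1 marks foreground.
#' @return Numeric \code{c(x, y)}: the mean column and row index of the
#'   foreground pixels (0-based, matching pixel coordinates).
#' @export
centroid_from_mask <- function(mask) {
  mask <- as.matrix(mask) != 0
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty ROI: mask has no foreground pixel")
  c(x = mean(idx[, "col"]) - 1, y = mean(idx[, "row"]) - 1)
}

#' Align the two camera streams on first centroid visibility
#'
#' The frame at which the body centroid first becomes visible under the top
#' camera defines time zero for both views; frames beyond the shorter stream
#' are dropped.
#'
#' @param top,rear \code{keypoint_table}s from the two views.
#' @param centroid \code{centroid_trace} accompanying the top view.
#' @return List with cropped \code{top}, \code{rear}, \code{centroid} and
#'   \code{start_frame} (the original index of the new frame 1).
#' @export
align_on_visibility <- function(top, rear, centroid) {
  stopifnot(inherits(top, "keypoint_table"), inherits(rear, "keypoint_table"),
            inherits(centroid, "centroid_trace"))
  v0 <- which(centroid$visible)[1]
  if (is.na(v0)) stop("alignment error: centroid never visible")
  n <- min(top$n_frames - v0 + 1L, rear$n_frames - v0 + 1L,
           centroid$n_frames - v0 + 1L)
  if (n < 1) stop("alignment error: no overlapping frames after cropping")
  keep <- v0:(v0 + n - 1L)
  crop_kp <- function(tb) keypoint_table(
    tb$view, tb$x[keep, , drop = FALSE], tb$y[keep, , drop = FALSE],
    tb$likelihood[keep, , drop = FALSE], tb$frame_rate)
  ct <- centroid_trace(centroid$x[keep], centroid$y[keep],
                       centroid$visible[keep], centroid$frame_rate)
  list(top = crop_kp(top), rear = crop_kp(rear), centroid = ct,
       start_frame = v0)
}

#' Extract the time-centered analysis window
#'
#' Returns the \code{n} samples centred on the series midpoint (the
#' conventional per-trial analysis window is 500 points). With an odd
#' surplus the extra sample is dropped from the end.
#'
#' @param series Numeric vector, matrix (frames in rows),
#'   \code{keypoint_table} or \code{centroid_trace}.
#' @param n Window length in samples (default 500).
#' @return The windowed object, with attribute \code{"window_start"} giving
#'   the index of the first kept sample.
#' @export
extract_centered_window <- function(series, n = 500) {
  len <- if (inherits(series, "keypoint_table")) series$n_frames
         else if (inherits(series, "centroid_trace")) series$n_frames
         else if (is.matrix(series)) nrow(series) else length(series)
  if (len < n) stop("window error: series length ", len, " < n = ", n)
  start <- floor((len - n) / 2) + 1L
  keep <- start:(start + n - 1L)
  out <- if (inherits(series, "keypoint_table")) {
    keypoint_table(series$view, series$x[keep, , drop = FALSE],
                   series$y[keep, , drop = FALSE],
                   series$likelihood[keep, , drop = FALSE], series$frame_rate)
  } else if (inherits(series, "centroid_trace")) {
    centroid_trace(series$x[keep], series$y[keep], series$visible[keep],
                   series$frame_rate)
  } else if (is.matrix(series)) series[keep, , drop = FALSE]
  else series[keep]
  attr(out, "window_start") <- start
  out
}

#' Construct trial metadata
#'
#' @param animal_id Animal label.
#' @param ridge_width Ridge width in mm (the study used 4, 5, 8, 10 mm plus
#'   a 45 mm control).
#' @param ridge_length Ridge length in mm (default 500).
#' @param tilt A \code{\link{tilt_profile}} or \code{NULL} for
#'   non-perturbation trials.
#' @param mm_per_pixel Named numeric: scale for \code{top} and \code{rear}
#'   views (mm per pixel).
#' @param ridge_midline_px Top-view lateral (y) pixel coordinate of the
#'   ridge midline.
#' @param trial_id Optional trial label.
#' @return An object of class \code{trial_meta}.
#' @export
trial_meta <- function(animal_id, ridge_width, ridge_length = 500,
                       tilt = NULL,
                       mm_per_pixel = c(top = 0.5, rear = 0.5),
                       ridge_midline_px = 0, trial_id = NULL) {
  if (!is.numeric(ridge_width) || ridge_width <= 0)
    stop("ridge_width must be positive (mm)")
  if (any(mm_per_pixel <= 0)) stop("mm_per_pixel must be positive")
  if (!is.null(tilt) && !inherits(tilt, "tilt_profile"))
    stop("tilt must be a tilt_profile or NULL")
  structure(list(
    animal_id = as.character(animal_id), trial_id = trial_id,
    ridge_width = ridge_width, ridge_length = ridge_length,
    tilt_present = !is.null(tilt),
    tilt_direction = if (is.null(tilt)) "none" else tilt$direction,
    tilt = tilt, mm_per_pixel = mm_per_pixel,
    ridge_midline_px = ridge_midline_px), class = "trial_meta")
}

#' @export
print.trial_meta <- function(x, ...) {
  cat("Trial", if (!is.null(x$trial_id)) x$trial_id else "", "— animal",
      x$animal_id, "\n")
  cat("  ridge:", x$ridge_width, "mm wide,", x$ridge_length, "mm long\n")
  if (x$tilt_present)
    cat("  tilt:", x$tilt$amplitude, "deg", x$tilt_direction, "over",
        x$tilt$duration, "s, onset frame", x$tilt$onset, "\n")
  else cat("  tilt: none\n")
  invisible(x)
}
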