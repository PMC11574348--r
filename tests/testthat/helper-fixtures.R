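# In-code fixtures shared across the suite.

# minimal keypoint table from per-bodypart coordinate lists
make_kp <- function(view, coords, likelihood = NULL, frame_rate = 300) {
  n <- length(coords[[1]]$x)
  x <- vapply(coords, function(cc) cc$x, numeric(n))
  y <- vapply(coords, function(cc) cc$y, numeric(n))
  colnames(x) <- names(coords)
  if (is.null(likelihood)) likelihood <- matrix(1, n, length(coords))
  keypoint_table(view, x, y, likelihood, frame_rate)
}

# straight-line centroid trace in pixels
make_centroid <- function(x, y, frame_rate = 300) {
  centroid_trace(x, y, rep(TRUE, length(x)), frame_rate)
}

flat_meta <- function(width = 4, mmpx = 1) {
  trial_meta("t1", ridge_width = width,
             mm_per_pixel = c(top = mmpx, rear = mmpx))
}

# deterministic IL-tilt simulation config used by several tests
il_config <- function(seed, ...) {
  sim_config(ridge_width = 5, tail_side = "right",
             tilt = tilt_profile(20, 0.190, "right", 331),
             seed = seed, ...)
}
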