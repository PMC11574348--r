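# brute-force local-maxima oracle with the same separation/prominence rules
brute_peaks <- function(x, min_sep, min_prom) {
  n <- length(x)
  cand <- which(vapply(2:(n - 1), function(i)
    x[i] > x[i - 1] && x[i] >= x[i + 1], logical(1))) + 1L
  prom <- vapply(cand, function(i) {
    left <- if (any(x[1:(i - 1)] > x[i])) {
      j <- max(which(x[1:(i - 1)] > x[i])); min(x[(j + 1):(i - 1)])
    } else min(x[1:(i - 1)])
    right <- if (any(x[(i + 1):n] > x[i])) {
      j <- i + min(which(x[(i + 1):n] > x[i])); min(x[(i + 1):(j - 1)])
    } else min(x[(i + 1):n])
    x[i] - max(left, right)
  }, numeric(1))
  cand <- cand[prom >= min_prom]
  keep <- integer(0)
  for (i in cand[order(x[cand], decreasing = TRUE)])
    if (all(abs(keep - i) >= min_sep)) keep <- c(keep, i)
  sort(keep)
}

test_that("step peaks of a 4 Hz stride appear every 75 frames", {
  t <- seq(0, 3 - 1 / 300, by = 1 / 300)
  x <- sin(2 * pi * 4 * t)
  ev <- detect_step_peaks(x, min_separation = 38, min_prominence = 0.5)
  expect_length(ev$event_frames, 12)
  expect_equal(unique(diff(ev$event_frames)), 75)
  expect_equal(ev$stride_period_frames, 75)
  expect_warning(detect_step_peaks(rep(1, 100)), "no step peaks")
})

test_that("prominence rejects fast low-amplitude ripple", {
  t <- seq(0, 2 - 1 / 300, by = 1 / 300)
  x <- sin(2 * pi * 4 * t) + 0.05 * sin(2 * pi * 40 * t)
  ev <- detect_step_peaks(x, min_separation = 10, min_prominence = 0.2)
  oracle <- brute_peaks(x, 10, 0.2)
  expect_equal(ev$event_frames, oracle)
  expect_length(ev$event_frames, 8)  # 4 Hz peaks only over 2 s
})

test_that("detector agrees with the brute-force oracle on rough noise", {
  set.seed(12)
  for (i in 1:5) {
    x <- hanning_smooth(rnorm(400), 10)
    got <- suppressWarnings(
      detect_step_peaks(x, min_separation = 20,
                        min_prominence = 0.1)$event_frames)
    expect_equal(got, brute_peaks(x, 20, 0.1))
  }
})

test_that("median inter-peak interval recovers the simulated stride period", {
  for (s in 1:10) {
    sim <- simulate_trial(sim_config(trial_duration = 5, seed = 400 + s))
    paw <- hanning_smooth(
      sim$top$x[, "left_hind_paw"] - sim$top$x[, "tail_base"], 10)
    ev <- detect_step_peaks(paw, min_separation = 38)
    expect_lte(abs(ev$stride_period_frames - 300 / 4), 1)
  }
})

test_that("epoch alignment centres windows on events and clips edges", {
  tr <- seq_len(300) * 1.0
  cyc <- align_epochs(tr, c(100), halfwidth = 50)
  expect_equal(cyc$n_epochs, 1)
  expect_equal(cyc$epochs[1, ], tr[50:150])
  expect_warning(align_epochs(tr, c(10), halfwidth = 50), "clipped")
  # periodic trace epoched at its period: identical epochs
  per <- rep(sin(2 * pi * (0:74) / 75), 10)
  cyc2 <- align_epochs(per, seq(100, 600, by = 75), halfwidth = 37)
  expect_equal(cyc2$n_epochs, 7)
  expect_true(all(apply(cyc2$epochs, 2, function(col)
    max(col) - min(col)) < 1e-12))
  # epoch count = events minus clipped, exactly
  ev <- c(10, 100, 200, 295)
  cyc3 <- suppressWarnings(align_epochs(tr, ev, halfwidth = 20))
  expect_equal(cyc3$n_epochs, 2L)
})

test_that("cycle statistics recover mean and range of sinusoidal epochs", {
  cyc <- align_epochs(rep(90, 200), c(100), halfwidth = 30)
  st <- cycle_stats(cyc)
  expect_equal(unname(st$trial["mean_position"]), 90)
  expect_equal(unname(st$trial["range"]), 0)
  # 90 + 10 sin over whole cycles
  n_cyc <- 4; per <- 50
  tr <- 90 + 10 * sin(2 * pi * seq(0, n_cyc, length.out = n_cyc * per + 1))
  cyc2 <- align_epochs(tr, 101, halfwidth = per)  # two whole cycles
  st2 <- cycle_stats(cyc2)
  expect_equal(unname(st2$trial["mean_position"]), 90, tolerance = 0.1 / 90)
  expect_equal(unname(st2$trial["range"]), 20, tolerance = 0.2 / 20)
  # range invariant to constant shifts; mean follows the shift
  cyc3 <- align_epochs(tr + 7, 101, halfwidth = per)
  st3 <- cycle_stats(cyc3)
  expect_equal(unname(st3$trial["range"]), unname(st2$trial["range"]))
  expect_equal(unname(st3$trial["mean_position"]),
               unname(st2$trial["mean_position"]) + 7)
  # averaging across epochs
  manual <- structure(list(epochs = rbind(c(0, 5, 10), c(10, 20, 40)),
                           n_epochs = 2L), class = "step_cycles")
  expect_equal(unname(cycle_stats(manual)$trial["range"]), 20)
  expect_error(
    cycle_stats(suppressWarnings(align_epochs(rep(1, 10), numeric(0), 2))),
    "empty")
})
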