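test_that("3-row-header CSV parses and round-trips at full precision", {
  set.seed(42)
  tb <- make_kp("top", list(
    nose = list(x = rnorm(10, 100), y = rnorm(10, 50)),
    tail_base = list(x = rnorm(10, 60), y = rnorm(10, 48))),
    likelihood = matrix(runif(20, 0.9, 1), 10, 2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_keypoint_table(tb, path)
  rt <- read_keypoint_table(path, "top")
  expect_equal(rt$n_frames, 10)
  expect_equal(rt$bodyparts, c("nose", "tail_base"))
  expect_equal(rt$x, tb$x)
  expect_equal(rt$y, tb$y)
  expect_equal(rt$likelihood, tb$likelihood)
})

test_that("malformed headers and invalid likelihoods are rejected", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("scorer,s,s,s", "wrong,a,a,a", "coords,x,y,likelihood",
               "0,1,2,0.99"), path)
  expect_error(read_keypoint_table(path, "top"), "row 2")
  writeLines(c("scorer,s,s,s", "bodyparts,a,a,a", "coords,x,likelihood,y",
               "0,1,2,0.99"), path)
  expect_error(read_keypoint_table(path, "top"), "row 3")
  writeLines(c("scorer,s,s,s", "bodyparts,a,a,a", "coords,x,y,likelihood",
               "0,1,2,1.2"), path)
  expect_error(read_keypoint_table(path, "top"), "integrity")
})

test_that("likelihood cutoff interpolates invalidated samples", {
  tb <- make_kp("rear",
    list(tail_base = list(x = c(0, 1, 9, 3), y = c(0, 0, 50, 0))),
    likelihood = matrix(c(1, 1, 0.5, 1), 4, 1))
  out <- apply_likelihood_cutoff(tb, 0.9)
  expect_equal(out$x[, 1], c(0, 1, 2, 3))
  expect_equal(out$y[, 1], c(0, 0, 0, 0))
  expect_equal(unname(attr(out, "n_replaced")["tail_base"]), 1L)
  # cutoff 0 leaves the table unchanged
  same <- apply_likelihood_cutoff(tb, 0)
  expect_equal(same$x, tb$x)
  # no valid sample at all
  bad <- make_kp("rear",
    list(tail_base = list(x = 1:4 * 1.0, y = 1:4 * 1.0)),
    likelihood = matrix(0.8, 4, 1))
  expect_error(apply_likelihood_cutoff(bad, 0.9), "unusable")
})

test_that("likelihood cutoff extends edges and is idempotent", {
  tb <- make_kp("rear",
    list(a = list(x = c(99, 5, 6, 99), y = c(99, 1, 2, 99))),
    likelihood = matrix(c(0.1, 1, 1, 0.2), 4, 1))
  out <- apply_likelihood_cutoff(tb, 0.9)
  expect_equal(out$x[, 1], c(5, 5, 6, 6))  # nearest-valid extension
  again <- apply_likelihood_cutoff(out, 0.9)
  expect_equal(again$x, out$x)
  expect_equal(again$y, out$y)
})

test_that("hanning smoothing preserves constants, means and impulse mass", {
  expect_equal(hanning_smooth(rep(5, 60), 10), rep(5, 60))
  expect_identical(hanning_smooth(1:20 * 1.0, 1), 1:20 * 1.0)
  imp <- rep(0, 41); imp[21] <- 1
  out <- hanning_smooth(imp, 9)
  # direct convolution oracle for the odd kernel
  w <- 0.5 * (1 - cos(2 * pi * (1:9) / 10)); w <- w / sum(w)
  expect_equal(out[17:25], w, tolerance = 1e-12)
  expect_equal(sum(out), 1, tolerance = 1e-10)
  # mean preservation on a constant-padded series (zero-phase even kernel)
  cp <- c(rep(3, 30), seq(3, 7, length.out = 40), rep(7, 30))
  expect_equal(mean(hanning_smooth(cp, 10)), mean(cp), tolerance = 1e-9)
  expect_error(hanning_smooth(rnorm(5), 10), "exceeds")
})

test_that("hanning smoothing is linear", {
  set.seed(7)
  a <- rnorm(100); b <- rnorm(100)
  expect_equal(hanning_smooth(2 * a + 3 * b, 10),
               2 * hanning_smooth(a, 10) + 3 * hanning_smooth(b, 10),
               tolerance = 1e-12)
})

test_that("visibility alignment crops both streams to a common origin", {
  n <- 100
  tb <- function(view) make_kp(view, list(a = list(x = 1:n * 1.0,
                                                   y = rep(0, n))))
  vis <- rep(TRUE, n); vis[1:36] <- FALSE
  cen <- centroid_trace(1:n * 1.0, rep(0, n), vis)
  al <- align_on_visibility(tb("top"), tb("rear"), cen)
  expect_equal(al$start_frame, 37)
  expect_equal(unname(al$top$x[1, 1]), 37)
  expect_equal(al$top$n_frames, 64)
  # visibility from frame 0: unchanged
  al0 <- align_on_visibility(tb("top"), tb("rear"),
                             centroid_trace(1:n * 1.0, rep(0, n),
                                            rep(TRUE, n)))
  expect_equal(al0$top$n_frames, n)
  # shorter stream bounds the aligned length
  short <- make_kp("rear", list(a = list(x = 1:80 * 1.0, y = rep(0, 80))))
  al2 <- align_on_visibility(tb("top"), short,
                             centroid_trace(1:n * 1.0, rep(0, n),
                                            rep(TRUE, n)))
  expect_equal(al2$rear$n_frames, 80)
  expect_equal(al2$top$n_frames, 80)
  expect_error(
    align_on_visibility(tb("top"), tb("rear"),
                        centroid_trace(1:n * 1.0, rep(0, n),
                                       rep(FALSE, n))),
    "never visible")
})

test_that("centered window extraction follows the midpoint rule", {
  s <- seq_len(700) * 1.0
  w <- extract_centered_window(s, 500)
  expect_equal(w[1], 101)
  expect_equal(w[500], 600)
  expect_identical(extract_centered_window(s[1:500], 500), s[1:500],
                   ignore_attr = TRUE)
  expect_error(extract_centered_window(s[1:499], 500), "window error")
})

test_that("mask centroid is the foreground pixel mean", {
  m <- matrix(0, 5, 5)
  m[1:2, 1:2] <- 1  # pixels (0,0),(0,1),(1,0),(1,1)
  expect_equal(unname(centroid_from_mask(m)), c(0.5, 0.5))
  m2 <- matrix(0, 10, 10); m2[4, 8] <- 1
  expect_equal(unname(centroid_from_mask(m2)), c(7, 3))
  expect_error(centroid_from_mask(matrix(0, 3, 3)), "empty ROI")
})
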