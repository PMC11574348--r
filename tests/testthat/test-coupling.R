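make_cc <- function(mat, bin_times = seq_len(ncol(mat))) {
  structure(list(matrix = mat, n_trials = 10, bin_times = bin_times),
            class = "crosscorrelogram")
}

test_that("correlogram diagonal is 1 for identical and -1 for negated epochs", {
  set.seed(21)
  e <- matrix(rnorm(20 * 15), 20, 15)
  cc <- build_correlogram(e, e)
  expect_equal(unname(diag(cc$matrix)), rep(1, 15), tolerance = 1e-12)
  cc2 <- build_correlogram(e, -e)
  expect_equal(unname(diag(cc2$matrix)), rep(-1, 15), tolerance = 1e-12)
  expect_true(all(abs(cc$matrix) <= 1 + 1e-12, na.rm = TRUE))
})

test_that("independent epochs stay within the permutation null envelope", {
  set.seed(22)
  n <- 50
  te <- matrix(rnorm(n * 12), n, 12)
  be <- matrix(rnorm(n * 12), n, 12)
  cc <- build_correlogram(te, be)
  expect_lt(abs(mean(cc$matrix)), 3 / sqrt(n))
  # permutation oracle: shuffling epoch order of one side leaves the
  # null-level magnitude unchanged
  perm <- build_correlogram(te, be[sample(n), ])
  expect_lt(abs(mean(perm$matrix)), 3 / sqrt(n))
})

test_that("correlations are invariant to per-epoch affine rescaling", {
  set.seed(23)
  te <- matrix(rnorm(30 * 10), 30, 10)
  be <- matrix(rnorm(30 * 10), 30, 10)
  cc <- build_correlogram(te, be)
  cc2 <- build_correlogram(3 * te - 100, 0.2 * be + 7)
  expect_equal(cc2$matrix, cc$matrix, tolerance = 1e-9)
  # swapping tail and body transposes the matrix
  cct <- build_correlogram(be, te)
  expect_equal(cct$matrix, t(cc$matrix), tolerance = 1e-12)
})

test_that("zero-variance bins yield undefined cells excluded from pools", {
  set.seed(24)
  te <- matrix(rnorm(20 * 6), 20, 6); te[, 3] <- 5
  be <- matrix(rnorm(20 * 6), 20, 6)
  cc <- build_correlogram(te, be)
  expect_true(all(is.na(cc$matrix[3, ])))
  reg <- find_extreme_regions(cc, 10)
  expect_false(any(reg$hotspot$cells[, "row"] == 3))
})

test_that("planted extreme blocks are recovered as hotspot and coldspot", {
  m <- matrix(0, 10, 10)
  m[3:5, 6:8] <- 0.9
  reg <- find_extreme_regions(make_cc(m), 5)
  expect_equal(reg$hotspot$size, 9)
  expect_setequal(paste(reg$hotspot$cells[, 1], reg$hotspot$cells[, 2]),
                  paste(rep(3:5, 3), rep(6:8, each = 3)))
  m2 <- matrix(0, 10, 10)
  m2[3:5, 6:8] <- -0.9
  reg2 <- find_extreme_regions(make_cc(m2), 5)
  expect_equal(reg2$coldspot$size, 9)
  expect_setequal(paste(reg2$coldspot$cells[, 1], reg2$coldspot$cells[, 2]),
                  paste(rep(3:5, 3), rep(6:8, each = 3)))
})

test_that("the larger of two disjoint passing regions wins", {
  m <- matrix(0, 12, 12)
  m[1:2, 1:2] <- 0.95          # size 4
  m[7:9, 7:8] <- 0.9           # size 6
  reg <- find_extreme_regions(make_cc(m), 5)
  expect_equal(reg$hotspot$size, 6)
  expect_true(all(reg$hotspot$cells[, "row"] %in% 7:9))
})

test_that("hotspot detection is unchanged by adding a constant", {
  set.seed(25)
  m <- matrix(rnorm(100), 10, 10)
  r1 <- find_extreme_regions(make_cc(m), 5)
  r2 <- find_extreme_regions(make_cc(m + 10), 5)
  expect_equal(r1$hotspot$cells, r2$hotspot$cells)
  expect_equal(r1$coldspot$cells, r2$coldspot$cells)
})

test_that("diagonal extraction indexes the square matrix correctly", {
  m <- diag(10)
  d <- correlogram_diagonal(make_cc(m, bin_times = 1:10 / 300))
  expect_equal(d$correlation, rep(1, 10))
  expect_equal(d$bin_time, 1:10 / 300)
  m2 <- matrix(0, 10, 10); m2[3:5, 3:5] <- 0.7
  d2 <- correlogram_diagonal(make_cc(m2))
  expect_equal(d2$correlation, c(0, 0, 0.7, 0.7, 0.7, rep(0, 5)))
})

test_that("anti-phase tail-hip simulations give negative zero-lag coupling", {
  neg <- vapply(1:20, function(s) {
    cf <- sim_config(ridge_width = 4, seed = s * 13)
    sim <- simulate_trial(cf)
    a <- analyze_trial(sim$top, sim$rear, sim$centroid, sim$meta)
    mt <- align_epochs(a$momentum$tail$values, a$events, a$halfwidth, 300)
    mb <- align_epochs(a$momentum$body$values, a$events, a$halfwidth, 300)
    cc <- build_correlogram(mt, mb)
    d <- correlogram_diagonal(cc)
    mean(d$correlation[abs(d$bin_time) <= 0.05], na.rm = TRUE)
  }, numeric(1))
  expect_gte(sum(neg < 0), 18)
})
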