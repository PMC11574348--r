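test_that("roll-plane tail angle follows the rear-view convention", {
  expect_equal(roll_tail_angle(c(0, 0), c(0, 10)), 180)   # tail up
  expect_equal(roll_tail_angle(c(0, 0), c(0, -10)), 0)    # tail down
  expect_equal(roll_tail_angle(c(0, 0), c(10, 0)), 90)    # horizontal right
  expect_equal(roll_tail_angle(c(0, 0), c(-10, 0)), 270)  # horizontal left
  # atan2 oracle for a diagonal
  expect_equal(roll_tail_angle(c(0, 0), c(10, -10)),
               atan2(10, 10) * 180 / pi)
  expect_error(roll_tail_angle(c(1, 1), c(1, 1)), "coincident")
})

test_that("yaw, hip, back and front angles reproduce their anchor values", {
  # yaw: 0 = straight back, +/-90 perpendicular
  expect_equal(yaw_tail_angle(c(0, 0), c(-10, 0)), 0)
  expect_equal(abs(yaw_tail_angle(c(0, 0), c(0, 7))), 90)
  expect_equal(abs(yaw_tail_angle(c(0, 0), c(-5, 5))), 45)
  # hip: 90 = horizontal, 0 = vertical
  expect_equal(hip_angle(c(0, 5), c(10, 5)), 90)
  expect_equal(hip_angle(c(0, 0), c(0, 8)), 0)
  expect_equal(hip_angle(c(0, 0), c(10, 10)), 45)
  # back: 0 = centroid straight ahead of the tail base
  expect_equal(back_angle(c(0, 0), c(10, 0)), 0)
  expect_equal(abs(back_angle(c(0, 0), c(10, 10))), 45)
  expect_equal(back_angle(c(0, 0), c(10, 5)),
               -back_angle(c(0, 0), c(10, -5)))  # reflection antisymmetry
  # front: 0 = nose straight ahead of the centroid
  expect_equal(front_angle(c(0, 0), c(10, 0)), 0)
  expect_equal(abs(front_angle(c(0, 0), c(0, 10))), 90)
  expect_equal(front_angle(c(2, 3), c(5, 6)), atan2(3, 3) * 180 / pi)
})

test_that("tail-on-body angle is the wrapped difference of yaw and back", {
  f <- function(tail, back) tail_on_body_angle(
    angle_trace("yaw_tail", tail), angle_trace("back", back))$values
  expect_equal(f(rep(30, 5), rep(30, 5)), rep(0, 5))
  expect_equal(f(90, 10), 80)
  expect_equal(f(-170, 20), 170)  # wraps across the branch cut
  expect_error(f(1:3, 1:4), "shape")
})

test_that("angle operations are invariant to translation and scaling", {
  set.seed(3)
  for (i in 1:10) {
    b <- rnorm(2); s <- b + rnorm(2)
    shift <- rnorm(2, sd = 50); k <- runif(1, 0.1, 8)
    expect_equal(roll_tail_angle(b, s),
                 roll_tail_angle(shift + k * b, shift + k * s),
                 tolerance = 1e-9)
    expect_equal(yaw_tail_angle(b, s), yaw_tail_angle(shift + k * b,
                                                      shift + k * s),
                 tolerance = 1e-9)
    expect_equal(hip_angle(b, s), hip_angle(shift + k * b, shift + k * s),
                 tolerance = 1e-9)
  }
})

test_that("mirroring reflects roll about vertical and double-mirroring is identity", {
  set.seed(4)
  for (i in 1:10) {
    b <- rnorm(2); s <- b + rnorm(2)
    th <- roll_tail_angle(b, s)
    mb <- b * c(-1, 1); ms <- s * c(-1, 1)
    expect_equal(roll_tail_angle(mb, ms) %% 360, (360 - th) %% 360,
                 tolerance = 1e-9)
  }
  traces <- list(
    roll_tail = angle_trace("roll_tail", runif(50, 0, 359)),
    yaw_tail = angle_trace("yaw_tail", runif(50, -179, 180)),
    hip = angle_trace("hip", runif(50, 1, 179)),
    back = angle_trace("back", runif(50, -179, 180)),
    hip_signed = runif(50, 1, 179))
  twice <- mirror_angle_traces(mirror_angle_traces(traces))
  for (nm in names(traces)) {
    a <- if (inherits(traces[[nm]], "angle_trace")) traces[[nm]]$values
         else traces[[nm]]
    b <- if (inherits(twice[[nm]], "angle_trace")) twice[[nm]]$values
         else twice[[nm]]
    expect_equal(b, a, tolerance = 1e-12)
  }
})

test_that("angular velocity matches analytic derivatives", {
  fps <- 300
  ramp <- seq(0, 90, length.out = fps + 1)  # 0 -> 90 deg over exactly 1 s
  v <- angular_velocity(angle_trace("hip", ramp, fps))
  expect_equal(v, rep(90, length(v)), tolerance = 1e-9)
  expect_equal(angular_velocity(angle_trace("hip", rep(42, 100), fps)),
               rep(0, 100))
  # sinusoid: peak velocity 2*pi*f*A deg/s within 0.5%
  f <- 2; A <- 30
  t <- seq(0, 3, by = 1 / fps)
  v2 <- angular_velocity(angle_trace("yaw_tail", A * sin(2 * pi * f * t),
                                     fps))
  expect_equal(max(v2), 2 * pi * f * A, tolerance = 5e-3)
  # velocity unaffected by constant offsets; robust to wrapping
  v3 <- angular_velocity(angle_trace("roll_tail",
                                     (A * sin(2 * pi * f * t) + 350) %% 360,
                                     fps))
  expect_equal(v3, v2, tolerance = 1e-9)
  expect_error(angular_velocity(angle_trace("hip", 5, fps)), "length")
})

test_that("laterality classification follows tail side vs tilt direction", {
  expect_equal(classify_laterality(290, "left")$label, "IL")
  expect_equal(classify_laterality(290, "right")$label, "CL")
  expect_equal(classify_laterality(70, "right")$label, "IL")
  # mirror image: tail and tilt both flipped leaves the label unchanged
  expect_equal(classify_laterality(360 - 290, "right")$label,
               classify_laterality(290, "left")$label)
  expect_error(classify_laterality(180, "left"), "unclassifiable")
})
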