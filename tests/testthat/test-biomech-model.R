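test_that("closed-form inertias match numerical mass integration", {
  m <- body_model()
  # rod about its base: discretize into 2e5 elements
  N <- 2e5
  x <- (seq_len(N) - 0.5) / N * m$tail_length
  I_rod_num <- sum(m$tail_mass / N * x^2)
  expect_equal(rod_inertia(m), I_rod_num, tolerance = 1e-6)
  # rod about its centre
  mc <- body_model(rod_axis = "center")
  xc <- x - m$tail_length / 2
  expect_equal(rod_inertia(mc), sum(m$tail_mass / N * xc^2),
               tolerance = 1e-6)
  # solid cylinder about its axis by polar quadrature:
  # I = integral rho r^2 dA with rho = M / (pi R^2), dA = r dr dtheta
  Nr <- 2e4
  r <- (seq_len(Nr) - 0.5) / Nr * m$body_radius
  dr <- m$body_radius / Nr
  rho_area <- m$body_mass / (pi * m$body_radius^2)
  I_cyl_num <- 2 * pi * rho_area * sum(r^3 * dr)
  expect_equal(cylinder_inertia(m), I_cyl_num, tolerance = 1e-6)
})

test_that("tail momentum evaluates the rod model at stated parameters", {
  m <- body_model()  # 0.5 g, 7 cm
  omega <- 2.2 * 2 * pi       # 2.2 rotations/s in rad/s
  L <- tail_momentum(omega, m)$values
  expect_equal(L, (1 / 3) * 5e-4 * 0.07^2 * omega)
  expect_equal(L, 1.129e-5, tolerance = 1e-3)
  expect_equal(tail_momentum(0, m)$values, 0)
  # quadratic in tail length at fixed omega
  m2 <- body_model(tail_length = 0.14)
  expect_equal(tail_momentum(omega, m2)$values, 4 * L)
})

test_that("body momentum evaluates the cylinder model", {
  m <- body_model()  # 20 g, 1 cm radius
  expect_equal(body_momentum(1, m)$values, 1e-6)
  expect_equal(body_momentum(0, m)$values, 0)
  m2 <- body_model(body_mass = 0.040)
  expect_equal(body_momentum(1, m2)$values, 2e-6)
  expect_error(tail_momentum(NaN, m), "non-finite")
})

test_that("perturbation momentum follows the tilt ramp and variant", {
  m <- body_model(platform_radius = 0.01)
  tp <- tilt_profile(20, 0.19, "right", onset = 1)
  expect_equal(tp$omega_rad_s, 20 * pi / 180 / 0.19, tolerance = 1e-12)
  n <- 300
  Lc <- perturbation_momentum(tp, m, n, 300,
                              variant = "cylinder_platform_radius")
  expect_equal(Lc$values[1], 0.5 * 0.0205 * 0.01^2 * tp$omega_rad_s)
  expect_equal(Lc$values[1], 1.883e-6, tolerance = 1e-3)
  # ramp ends after 0.19 s -> momentum back to zero
  expect_equal(Lc$values[ceiling(0.19 * 300) + 2], 0)
  expect_equal(perturbation_momentum(tilt_profile(0, 0.19, "right", 1),
                                     m, n, 300)$values, rep(0, n))
  # point mass and parallel-axis variants
  Lp <- perturbation_momentum(tp, m, n, 300, variant = "point_mass_at_edge")
  expect_equal(Lp$values[1], 0.0205 * 1e-4 * tp$omega_rad_s)
  La <- perturbation_momentum(tp, m, n, 300,
                              variant = "cylinder_plus_parallel_axis")
  expect_equal(La$values[1],
               (0.5 * 0.0205 * 1e-4 + 0.0205 * 1e-4) * tp$omega_rad_s)
  # left tilts are negative under signed output
  Ll <- perturbation_momentum(tilt_profile(20, 0.19, "left", 1), m, n, 300)
  expect_true(all(Ll$values[1:10] < 0))
})

test_that("momentum integration is trapezoidal, additive and mode-aware", {
  fps <- 300
  tr <- structure(
    list(source = "tail", values = rep(2, 151), frame_rate = fps),
    class = "momentum_trace")
  expect_equal(integrate_momentum(tr, c(0, 0.5), "signed"), 1.0)
  # antisymmetric swing: signed integral ~ 0, absolute > 0
  t <- seq(0, 1, by = 1 / fps)
  sw <- structure(list(source = "tail", values = sin(2 * pi * t),
                       frame_rate = fps), class = "momentum_trace")
  expect_equal(integrate_momentum(sw, c(0, 1), "signed"), 0,
               tolerance = 1e-6)
  expect_gt(integrate_momentum(sw, c(0, 1), "absolute"), 0.5)
  # additivity over adjacent windows
  expect_equal(integrate_momentum(sw, c(0, 0.3)) +
                 integrate_momentum(sw, c(0.3, 1)),
               integrate_momentum(sw, c(0, 1)), tolerance = 1e-12)
  # trapezoid converges to the analytic integral at O(dt^2)
  half_sine <- function(fps) {
    tt <- seq(0, 1, by = 1 / fps)
    structure(list(source = "tail", values = sin(pi * tt),
                   frame_rate = fps), class = "momentum_trace")
  }
  err <- vapply(c(100, 200, 400), function(f)
    abs(integrate_momentum(half_sine(f), c(0, 1)) - 2 / pi), numeric(1))
  expect_lt(err[3], err[1] / 10)  # better than O(dt)
  expect_error(integrate_momentum(sw, c(0.5, 0.5)), "empty window")
})

test_that("relative momentum normalizes by the perturbation total", {
  expect_equal(unname(relative_momentum(1, 0, 1)["sum"]), 1.0)
  expect_equal(unname(relative_momentum(0, 0, 2)["sum"]), 0)
  r <- relative_momentum(0.5, 0.3, 1)
  expect_equal(unname(r["sum"]), 0.8)
  expect_true(all(is.na(relative_momentum(1, 1, 0))))
})

test_that("phase splitting divides the response at the ramp end", {
  fps <- 300
  tr <- structure(list(source = "sum", values = rep(1, 400),
                       frame_rate = fps), class = "momentum_trace")
  ph <- split_phases(tr, tilt_profile(20, 0.19, "right", onset = 1),
                     response_window = 0.5)
  expect_equal(unname(ph["early"]), 0.19, tolerance = 1e-9)
  expect_equal(unname(ph["late"]), 0.31, tolerance = 1e-9)
  z <- structure(list(source = "sum", values = rep(0, 400),
                      frame_rate = fps), class = "momentum_trace")
  expect_equal(unname(split_phases(z, tilt_profile(20, 0.19, "right", 1))),
               c(0, 0))
  # impulse confined to the ramp leaves the late phase empty
  v <- rep(0, 400); v[10:20] <- 5
  imp <- structure(list(source = "tail", values = v, frame_rate = fps),
                   class = "momentum_trace")
  ph2 <- split_phases(imp, tilt_profile(20, 0.19, "right", 1))
  expect_equal(unname(ph2["late"]), 0)
  expect_gt(unname(ph2["early"]), 0)
})

test_that("sum trace equals tail plus body exactly", {
  set.seed(2)
  om_t <- rnorm(200); om_b <- rnorm(200)
  m <- body_model()
  lt <- tail_momentum(om_t, m); lb <- body_momentum(om_b, m)
  ls <- sum_momentum(lt, lb)
  expect_identical(ls$values, lt$values + lb$values)
})
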