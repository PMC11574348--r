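# Rod-and-cylinder angular-momentum model.
#
# The tail is approximated as a uniform rod (length l, mass m_t) rotating
# about an axis through its base, the body as a solid cylinder (radius r_b,
# mass m_b) rotating about its central axis, and the ridge tilt as a
# rotation imposed on the whole animal sitting at the edge of the tilting
# platform. Angular momentum L = I * omega, in kg m^2 / s.

#' Anatomical body model
#'
#' Default masses and dimensions follow carcass measurements of adult mice:
#' tail 0.5 g and 7 cm, body 20 g with a 2 cm diameter.
#'
#' @param tail_mass Tail mass, kg (default 5e-4).
#' @param tail_length Tail length, m (default 0.07).
#' @param body_mass Body mass (without tail), kg (default 0.020).
#' @param body_radius Body cylinder radius, m (default 0.01).
#' @param platform_radius Effective platform radius for the perturbation
#'   model, m (default: the body radius; see
#'   \code{\link{perturbation_momentum}}).
#' @param rod_axis Tail rod rotation axis: \code{"base"} (I = m l^2 / 3;
#'   the swing starts from the tail base) or \code{"center"}
#'   (I = m l^2 / 12).
#' @return An object of class \code{body_model}.
#' @export
body_model <- function(tail_mass = 5e-4, tail_length = 0.07,
                       body_mass = 0.020, body_radius = 0.01,
                       platform_radius = body_radius,
                       rod_axis = c("base", "center")) {
  rod_axis <- match.arg(rod_axis)
  vals <- c(tail_mass, tail_length, body_mass, body_radius, platform_radius)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all body-model parameters must be strictly positive")
  structure(list(tail_mass = tail_mass, tail_length = tail_length,
                 body_mass = body_mass, body_radius = body_radius,
                 platform_radius = platform_radius, rod_axis = rod_axis),
            class = "body_model")
}

#' Moment of inertia of the tail rod
#' @param model A \code{body_model}.
#' @return kg m^2: m l^2 / 3 about the base (default) or m l^2 / 12 about
#'   the centre.
#' @export
rod_inertia <- function(model) {
  f <- if (model$rod_axis == "base") 1 / 3 else 1 / 12
  f * model$tail_mass * model$tail_length^2
}

#' Moment of inertia of the body cylinder about its central axis
#' @param model A \code{body_model}.
#' @return kg m^2: m r^2 / 2.
#' @export
cylinder_inertia <- function(model) {
  0.5 * model$body_mass * model$body_radius^2
}

#' Ridge tilt profile
#'
#' The platform ramps at constant angular velocity (amplitude / duration)
#' from the onset frame for the stated duration, then stays; baseline
#' profiles are 10, 20 or 30 deg over 150, 190 or 230 ms.
#'
#' @param amplitude Tilt amplitude, degrees.
#' @param duration Ramp duration, seconds.
#' @param direction \code{"left"} or \code{"right"}.
#' @param onset Onset frame index (1-based).
#' @return An object of class \code{tilt_profile} with the ramp angular
#'   speed \code{omega_rad_s} (rad/s, unsigned).
#' @export
tilt_profile <- function(amplitude = 20, duration = 0.190,
                         direction = c("left", "right"), onset = 1) {
  direction <- match.arg(direction)
  if (duration <= 0) stop("tilt duration must be positive")
  structure(list(amplitude = amplitude, duration = duration,
                 direction = direction, onset = onset,
                 omega_rad_s = amplitude * pi / 180 / duration),
            class = "tilt_profile")
}

momentum_trace_new <- function(source, values, frame_rate) {
  structure(list(source = source, values = as.numeric(values),
                 frame_rate = frame_rate), class = "momentum_trace")
}

#' @export
print.momentum_trace <- function(x, ...) {
  cat("Momentum trace (", x$source, "): ", length(x$values), " frames, peak |L| = ",
      format(max(abs(x$values)), digits = 4), " kg m^2/s\n", sep = "")
  invisible(x)
}

#' Tail angular momentum
#'
#' L(t) = I_rod * omega(t) with the rod pivoting about its base
#' (I = m_t l^2 / 3) by default.
#'
#' @param omega_rad_s Tail angular velocity series, rad/s (roll-plane tail
#'   angle derivative).
#' @param model A \code{body_model}.
#' @param frame_rate Frames per second.
#' @return A \code{momentum_trace} with source \code{"tail"}.
#' @export
tail_momentum <- function(omega_rad_s, model = body_model(),
                          frame_rate = 300) {
  if (any(!is.finite(omega_rad_s)))
    stop("non-finite angular velocity in tail momentum")
  momentum_trace_new("tail", rod_inertia(model) * omega_rad_s, frame_rate)
}

#' Body angular momentum
#'
#' L(t) = (1/2) m_b r_b^2 * omega(t), the solid cylinder about its central
#' axis.
#'
#' @param omega_rad_s Body roll angular velocity series, rad/s (signed hip
#'   inclination derivative).
#' @inheritParams tail_momentum
#' @return A \code{momentum_trace} with source \code{"body"}.
#' @export
body_momentum <- function(omega_rad_s, model = body_model(),
                          frame_rate = 300) {
  if (any(!is.finite(omega_rad_s)))
    stop("non-finite angular velocity in body momentum")
  momentum_trace_new("body", cylinder_inertia(model) * omega_rad_s,
                     frame_rate)
}

#' Perturbation angular momentum
#'
#' Momentum imparted to the animal (total mass M = m_b + m_t) by the
#' tilting platform, L(t) = I * omega_p(t), with omega_p the platform
#' ramp speed during the tilt and zero elsewhere. Three readings of the
#' platform inertia are implemented:
#' \describe{
#'   \item{cylinder_platform_radius}{I = (1/2) M r_p^2 (cylinder of the
#'     platform radius).}
#'   \item{point_mass_at_edge}{I = M d^2, the animal as a point mass at
#'     distance d = r_p from the rotation axis.}
#'   \item{cylinder_plus_parallel_axis}{I = (1/2) M r_b^2 + M d^2 with
#'     d = r_p: the body cylinder displaced to the platform edge
#'     (parallel-axis theorem). Default, since the animal's mass sits a
#'     finite distance off the tilt axis.}
#' }
#'
#' @param tilt A \code{tilt_profile}.
#' @param model A \code{body_model}; \code{platform_radius} supplies d/r_p.
#' @param n_frames Length of the output trace.
#' @param frame_rate Frames per second.
#' @param variant Inertia variant (see Details).
#' @param signed If \code{TRUE}, left tilts are negative.
#' @return A \code{momentum_trace} with source \code{"perturbation"} and
#'   attribute \code{"variant"}.
#' @export
perturbation_momentum <- function(tilt, model = body_model(), n_frames,
                                  frame_rate = 300,
                                  variant = c("cylinder_plus_parallel_axis",
                                              "cylinder_platform_radius",
                                              "point_mass_at_edge"),
                                  signed = TRUE) {
  stopifnot(inherits(tilt, "tilt_profile"))
  variant <- match.arg(variant)
  M <- model$body_mass + model$tail_mass
  d <- model$platform_radius
  I <- switch(variant,
    cylinder_platform_radius = 0.5 * M * d^2,
    point_mass_at_edge = M * d^2,
    cylinder_plus_parallel_axis = 0.5 * M * model$body_radius^2 + M * d^2)
  t_rel <- (seq_len(n_frames) - tilt$onset) / frame_rate
  omega <- ifelse(t_rel >= 0 & t_rel < tilt$duration, tilt$omega_rad_s, 0)
  sgn <- if (signed && tilt$direction == "left") -1 else 1
  out <- momentum_trace_new("perturbation", sgn * I * omega, frame_rate)
  attr(out, "variant") <- variant
  out
}

#' Sum of tail and body momentum traces
#'
#' @param tail,body \code{momentum_trace} objects of equal length.
#' @return A \code{momentum_trace} with source \code{"sum"}.
#' @export
sum_momentum <- function(tail, body) {
  stopifnot(length(tail$values) == length(body$values))
  momentum_trace_new("sum", tail$values + body$values, tail$frame_rate)
}

#' Integrate a momentum trace over a time window
#'
#' Trapezoidal time-integral of L (signed) or |L| (absolute) over
#' [t0, t1] seconds relative to the start of the trace.
#'
#' @param trace A \code{momentum_trace}.
#' @param window Numeric \code{c(t0, t1)}, seconds; t1 > t0, within the
#'   trace.
#' @param mode \code{"signed"} or \code{"absolute"}.
#' @return Integrated momentum, kg m^2 / s * s.
#' @export
integrate_momentum <- function(trace, window, mode = c("signed", "absolute")) {
  mode <- match.arg(mode)
  stopifnot(inherits(trace, "momentum_trace"), length(window) == 2)
  if (window[2] <= window[1]) stop("parameter error: empty window")
  n <- length(trace$values)
  t <- (seq_len(n) - 1) / trace$frame_rate
  if (window[1] < 0 || window[2] > t[n])
    stop("parameter error: window outside trace")
  v <- if (mode == "absolute") abs(trace$values) else trace$values
  # exact trapezoid on the piecewise-linear interpolant, with fractional
  # endpoints handled by interpolation
  grid <- sort(unique(c(window, t[t > window[1] & t < window[2]])))
  vg <- stats::approx(t, v, xout = grid)$y
  sum(diff(grid) * (utils::head(vg, -1) + utils::tail(vg, -1)) / 2)
}

#' Relative (perturbation-normalized) momentum
#'
#' Window totals for tail and body normalized by the perturbation total:
#' tail/pert, body/pert and (tail+body)/pert.
#'
#' @param tail_total,body_total,pert_total Integrated momenta (same mode
#'   and window).
#' @return Named numeric vector \code{c(tail, body, sum)}; all \code{NA}
#'   when the perturbation total is zero (non-tilt trials).
#' @export
relative_momentum <- function(tail_total, body_total, pert_total) {
  if (!is.finite(pert_total) || pert_total == 0)
    return(c(tail = NA_real_, body = NA_real_, sum = NA_real_))
  c(tail = tail_total / pert_total, body = body_total / pert_total,
    sum = (tail_total + body_total) / pert_total)
}

#' Split a momentum trace into early and late response phases
#'
#' Early phase: the tilt ramp itself, [onset, onset + duration]. Late
#' phase: from ramp end to the end of the response window (the response is
#' analysed over the 0.5 s window after tilt onset).
#'
#' @param trace A \code{momentum_trace}.
#' @param tilt A \code{tilt_profile} (onset interpreted on the trace's
#'   frame indexing).
#' @param response_window Response window length after onset, seconds
#'   (default 0.5).
#' @param mode Integration mode, as in \code{\link{integrate_momentum}}.
#' @return Named numeric vector \code{c(early, late)}.
#' @export
split_phases <- function(trace, tilt, response_window = 0.5,
                         mode = "signed") {
  stopifnot(inherits(trace, "momentum_trace"), inherits(tilt, "tilt_profile"))
  t0 <- (tilt$onset - 1) / trace$frame_rate
  t_end <- (length(trace$values) - 1) / trace$frame_rate
  t1 <- t0 + tilt$duration
  t2 <- t0 + response_window
  if (t2 > t_end) {
    warning("response window exceeds trace; truncating")
    t2 <- t_end
    t1 <- min(t1, t_end)
  }
  early <- if (t1 > t0) integrate_momentum(trace, c(t0, t1), mode) else 0
  late <- if (t2 > t1) integrate_momentum(trace, c(t1, t2), mode) else 0
  c(early = early, late = late)
}

#' Convert deg/s to rad/s
#' @param x Angular velocity in deg/s.
#' @return rad/s.
#' @export
deg2rad_s <- function(x) x * pi / 180
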