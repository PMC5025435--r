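# Parametrized Semont maneuver kinematics.
#
# The maneuver has four phases: (1) first movement from upright to
# +(90 + alpha_plus) degrees, (2) a resting period T_p, (3) second movement by
# -(180 + 2*alpha_plus) degrees to -(90 + alpha_plus), and (4) a final
# observation period.  Orientation beta is measured in the canal plane;
# beta = 0 is upright and positive beta is the first-movement direction.
# Movements are constant-velocity plateaus, optionally with linear
# acceleration ramps (trapezoidal velocity profile) for manually executed
# maneuvers.  A pivot offset L > 0 places the rotation centre below the canal
# (a patient pivoting about the pelvis); L = 0 is the stepper-motor setup with
# the rotation centre at the canal centre.

#' Parametrized Semont maneuver specification
#'
#' @param extension_angle_deg Extension angle alpha_plus in degrees
#'   (0 to 45): how far each movement extends beyond the horizontal.
#' @param maneuver_velocity_deg_s Angular maneuver velocity v in degrees/s
#'   (plateau velocity; 0 < v <= 360).
#' @param resting_time_s Resting time T_p between the two movements (s).
#' @param final_observation_s Final observation window after the second
#'   movement (s); must be long enough for the particle to reach a terminal
#'   compartment.
#' @param pivot_offset_m Distance from the rotation centre to the canal
#'   centre (m); 0 for the stepper-motor setup, 0.72 for the lever arm.
#' @param ramp_time_s Duration of the linear acceleration/deceleration ramps
#'   at the start and end of each movement (s); 0 gives ideal constant
#'   velocity.
#' @return An object of class `maneuver_spec`.
#' @examples
#' maneuver_spec(20, 135, resting_time_s = 45)
#' @export
maneuver_spec <- function(extension_angle_deg, maneuver_velocity_deg_s,
                          resting_time_s, final_observation_s = 60,
                          pivot_offset_m = 0, ramp_time_s = 0) {
  .check_range(extension_angle_deg, "extension_angle_deg", 0, 45)
  .check_positive(maneuver_velocity_deg_s, "maneuver_velocity_deg_s")
  .check_range(maneuver_velocity_deg_s, "maneuver_velocity_deg_s", 1e-6, 720)
  .check_positive(resting_time_s, "resting_time_s", strict = FALSE)
  .check_positive(final_observation_s, "final_observation_s")
  .check_positive(pivot_offset_m, "pivot_offset_m", strict = FALSE)
  .check_positive(ramp_time_s, "ramp_time_s", strict = FALSE)
  structure(
    list(extension_angle_deg = extension_angle_deg,
         maneuver_velocity_deg_s = maneuver_velocity_deg_s,
         resting_time_s = resting_time_s,
         final_observation_s = final_observation_s,
         pivot_offset_m = pivot_offset_m,
         ramp_time_s = ramp_time_s),
    class = "maneuver_spec")
}

# One movement from beta_from to beta_to at plateau velocity v (deg/s) with
# symmetric linear ramps of duration `ramp`.  Returns a list of segment rows
# (duration, beta0, omega0, accel) with omega piecewise linear, so beta is
# piecewise quadratic and exactly evaluable.
.move_segments <- function(beta_from, beta_to, v, ramp) {
  sweep <- abs(beta_to - beta_from)
  s <- sign(beta_to - beta_from)
  if (ramp <= 0) {
    return(list(c(dur = sweep / v, beta0 = beta_from, omega0 = s * v,
                  accel = 0)))
  }
  if (v * ramp >= sweep) {
    stop("invalid parameter `ramp_time_s`: ramps sweep the whole movement; ",
         "reduce ramp_time_s or maneuver velocity", call. = FALSE)
  }
  a <- s * v / ramp
  list(
    c(dur = ramp, beta0 = beta_from, omega0 = 0, accel = a),
    c(dur = (sweep - v * ramp) / v, beta0 = beta_from + s * v * ramp / 2,
      omega0 = s * v, accel = 0),
    c(dur = ramp, beta0 = beta_to - s * v * ramp / 2, omega0 = s * v,
      accel = -a))
}

# Assemble the piecewise-quadratic orientation profile.  stop1/stop2 are the
# realized magnitudes of the two stop angles (nominally both 90 + alpha_plus);
# the synthetic operator perturbs them independently.
.build_segments <- function(stop1, stop2, v, resting_time, final_obs, ramp) {
  segs <- list()
  add <- function(rows, phase) {
    for (r in rows) segs[[length(segs) + 1L]] <<- c(r, phase = phase)
  }
  add(.move_segments(0, stop1, v, ramp), "move1")
  if (resting_time > 0) {
    add(list(c(dur = resting_time, beta0 = stop1, omega0 = 0, accel = 0)),
        "rest")
  }
  add(.move_segments(stop1, -stop2, v, ramp), "move2")
  add(list(c(dur = final_obs, beta0 = -stop2, omega0 = 0, accel = 0)),
      "final")
  dur <- vapply(segs, function(s) as.numeric(s[["dur"]]), 0)
  keep <- dur > 1e-12
  segs <- segs[keep]
  dur <- dur[keep]
  t0 <- cumsum(c(0, dur[-length(dur)]))
  data.frame(
    t0 = t0,
    t1 = t0 + dur,
    beta0_deg = vapply(segs, function(s) as.numeric(s[["beta0"]]), 0),
    omega0_deg_s = vapply(segs, function(s) as.numeric(s[["omega0"]]), 0),
    accel_deg_s2 = vapply(segs, function(s) as.numeric(s[["accel"]]), 0),
    phase = vapply(segs, function(s) s[["phase"]], ""),
    stringsAsFactors = FALSE)
}

# Exact piecewise evaluation of the orientation profile at arbitrary times.
.eval_segments <- function(segments, t) {
  i <- findInterval(t, segments$t0)
  i[i < 1L] <- 1L
  i[i > nrow(segments)] <- nrow(segments)
  dt <- t - segments$t0[i]
  list(
    index = i,
    beta_deg = segments$beta0_deg[i] + segments$omega0_deg_s[i] * dt +
      0.5 * segments$accel_deg_s2[i] * dt^2,
    omega_deg_s = segments$omega0_deg_s[i] + segments$accel_deg_s2[i] * dt,
    accel_deg_s2 = segments$accel_deg_s2[i],
    phase = segments$phase[i])
}

.trace_from_segments <- function(segments, spec, sample_step,
                                 realized = NULL) {
  total <- segments$t1[nrow(segments)]
  times <- seq(0, total, by = sample_step)
  if (times[length(times)] < total - 1e-12) times <- c(times, total)
  ev <- .eval_segments(segments, times)
  samples <- data.frame(
    time_s = times,
    beta_deg = ev$beta_deg,
    omega_deg_s = ev$omega_deg_s,
    alpha_deg_s2 = ev$accel_deg_s2,
    phase = ev$phase,
    stringsAsFactors = FALSE)
  structure(
    list(segments = segments, samples = samples, spec = spec,
         sample_step = sample_step, total_s = total,
         realized = realized),
    class = "orientation_trace")
}

#' Build the orientation trace of a parametrized Semont maneuver
#'
#' Realizes a [maneuver_spec()] as a four-phase orientation time series
#' (move1, rest, move2, final).  The profile is stored both as an exactly
#' evaluable piecewise-quadratic segment table (used by the integrator) and
#' as a uniformly sampled series.
#'
#' @param spec A [maneuver_spec()].
#' @param sample_step Sampling step of the exported series (s); at most
#'   0.01 s.
#' @return An object of class `orientation_trace` with elements `segments`,
#'   `samples` (columns `time_s`, `beta_deg`, `omega_deg_s`, `alpha_deg_s2`,
#'   `phase`), `spec`, `total_s` and `realized` (the stop angles, plateau
#'   velocity and resting time actually used).
#' @examples
#' tr <- build_trace(maneuver_spec(20, 90, 5, final_observation_s = 1))
#' range(tr$samples$beta_deg)  # -110 .. 110
#' @export
build_trace <- function(spec, sample_step = 0.001) {
  stopifnot(inherits(spec, "maneuver_spec"))
  if (!is.numeric(sample_step) || sample_step <= 0 || sample_step > 0.01) {
    stop("invalid parameter `sample_step`: must be in (0, 0.01] s",
         call. = FALSE)
  }
  stop_angle <- 90 + spec$extension_angle_deg
  segments <- .build_segments(stop_angle, stop_angle,
                              spec$maneuver_velocity_deg_s,
                              spec$resting_time_s, spec$final_observation_s,
                              spec$ramp_time_s)
  .trace_from_segments(segments, spec, sample_step,
                       realized = list(stop1_deg = stop_angle,
                                       stop2_deg = stop_angle,
                                       velocity_deg_s =
                                         spec$maneuver_velocity_deg_s,
                                       resting_time_s = spec$resting_time_s))
}

#' @export
print.orientation_trace <- function(x, ...) {
  cat("<orientation_trace>", nrow(x$samples), "samples over",
      format(x$total_s), "s;",
      "stops +", format(x$realized$stop1_deg), "/ -",
      format(x$realized$stop2_deg), "deg; v =",
      format(x$realized$velocity_deg_s), "deg/s; T_p =",
      format(x$realized$resting_time_s), "s\n")
  invisible(x)
}

#' @export
as.data.frame.orientation_trace <- function(x, ...) x$samples

#' Rigid-body kinematics and inertial acceleration at the canal centre
#'
#' Evaluates orientation, angular velocity, angular acceleration, and the
#' inertial (pseudo-)acceleration at the canal centre for a pivot offset L.
#' In the canal frame the inertial acceleration has a tangential component
#' `-L * d(omega)/dt` (perpendicular to the arm) and a centrifugal component
#' `+L * omega^2` directed from the pivot towards the canal; both vanish for
#' L = 0 (stepper motor, pivot at the canal centre) and during rest phases.
#' Adding this vector to gravity gives the effective gravity that drives
#' particle settling.
#'
#' @param trace An [build_trace()] orientation trace.
#' @param t Time(s) within the trace span (s).
#' @param pivot_offset Pivot offset L (m); defaults to the value in the
#'   trace's maneuver specification.
#' @return A data frame with columns `time_s`, `beta_deg`, `omega_deg_s`,
#'   `alpha_deg_s2`, `inertial_tangential_m_s2`, `inertial_centrifugal_m_s2`,
#'   and `phase`.
#' @examples
#' tr <- build_trace(maneuver_spec(20, 90, 5, pivot_offset_m = 0.72))
#' kinematics_at(tr, c(0.5, 2))
#' @export
kinematics_at <- function(trace, t, pivot_offset = NULL) {
  stopifnot(inherits(trace, "orientation_trace"))
  if (is.null(pivot_offset)) pivot_offset <- trace$spec$pivot_offset_m
  if (any(t < -1e-9) || any(t > trace$total_s + 1e-9)) {
    stop("time out of range: `t` must lie within [0, ", format(trace$total_s),
         "] s", call. = FALSE)
  }
  ev <- .eval_segments(trace$segments, t)
  omega_rad <- .deg2rad(ev$omega_deg_s)
  accel_rad <- .deg2rad(ev$accel_deg_s2)
  data.frame(
    time_s = t,
    beta_deg = ev$beta_deg,
    omega_deg_s = ev$omega_deg_s,
    alpha_deg_s2 = ev$accel_deg_s2,
    inertial_tangential_m_s2 = -pivot_offset * accel_rad,
    inertial_centrifugal_m_s2 = pivot_offset * omega_rad^2,
    phase = ev$phase,
    stringsAsFactors = FALSE)
}

# Effective gravity in lab coordinates at time t for one segment's constants.
# The arm direction (pivot -> canal) is u(beta) = (-sin beta, cos beta); the
# pseudo-acceleration added to gravity is L*omega^2*u - L*beta_dd*du/dbeta.
# Returns c(gx, gy) with gravity = (0, -g).
.effective_gravity <- function(beta_rad, omega_rad, accel_rad, L, g) {
  if (L == 0 || (omega_rad == 0 && accel_rad == 0)) return(c(0, -g))
  sb <- sin(beta_rad)
  cb <- cos(beta_rad)
  c(-L * omega_rad^2 * sb + L * accel_rad * cb,
    -g + L * omega_rad^2 * cb + L * accel_rad * sb)
}
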