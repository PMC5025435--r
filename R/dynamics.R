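# Overdamped transport of a single canalith along the duct centreline.
#
# The particle position is the arc coordinate psi (degrees) along the slender
# duct, measured from the ampulla end (psi = 0) to the utricle opening
# (psi = duct_span_deg).  The endolymph is assumed to co-rotate rigidly with
# the canal, so the particle co-moves with the canal except for Stokes slip
# towards the gravitationally lowest point of the duct circle:
#
#   d(psi)/dt = -(v_s,eff / R) * sin(psi - psi_bottom,eff(t))
#
# in radian measure.  Under plain gravity the lowest point sits at
# psi_bottom = (90 - elevation) + beta; with a pivot offset the effective
# gravity (gravity + centrifugal + tangential inertial terms) both tilts
# psi_bottom and rescales the settling speed by |g_eff|/g.  The duct ends are
# absorbing: psi = 0 is the ampulla (maneuver failure), psi = span is the
# utricle (success).

#' Semicircular canal duct geometry
#'
#' Circular duct in the maneuver plane.  Defaults describe the five-fold
#' scaled bench model: major radius 16 mm, slender duct radius 0.75 mm.  The
#' duct spans `duct_span_deg` of arc from the ampulla end to the utricle
#' opening; in the upright position the ampulla sits
#' `upright_ampulla_elevation_deg` below the horizontal.
#'
#' @param major_radius Radius R of the duct circle (m).
#' @param duct_radius Inner radius a of the slender duct (m); must be small
#'   against R.
#' @param duct_span_deg Arc span Psi of the duct in degrees (180 < Psi < 360).
#'   The physical model's exact span is not critical as long as it exceeds
#'   the post-first-movement rest position and stays below the utricle-side
#'   equilibrium after the second movement.
#' @param upright_ampulla_elevation_deg Angle of the ampulla below the
#'   horizontal at upright orientation (degrees); 32 matches the canal
#'   orientation of an upright head.
#' @return An object of class `canal_geometry`.
#' @export
canal_geometry <- function(major_radius = 16e-3, duct_radius = 0.75e-3,
                           duct_span_deg = 240,
                           upright_ampulla_elevation_deg = 32) {
  .check_positive(major_radius, "major_radius")
  .check_positive(duct_radius, "duct_radius")
  if (duct_radius >= major_radius / 2) {
    stop("invalid parameter `duct_radius`: must be small against ",
         "`major_radius`", call. = FALSE)
  }
  if (!is.numeric(duct_span_deg) || duct_span_deg <= 180 ||
      duct_span_deg >= 360) {
    stop("invalid parameter `duct_span_deg`: must lie in (180, 360)",
         call. = FALSE)
  }
  .check_range(upright_ampulla_elevation_deg,
               "upright_ampulla_elevation_deg", 0, 90)
  structure(
    list(major_radius = major_radius, duct_radius = duct_radius,
         duct_span_deg = duct_span_deg,
         upright_ampulla_elevation_deg = upright_ampulla_elevation_deg),
    class = "canal_geometry")
}

#' @export
print.canal_geometry <- function(x, ...) {
  cat("<canal_geometry> R =", format(x$major_radius * 1e3), "mm, a =",
      format(x$duct_radius * 1e3), "mm, span =", x$duct_span_deg,
      "deg, upright ampulla elevation =", x$upright_ampulla_elevation_deg,
      "deg\n")
  invisible(x)
}

#' Arc coordinate of the gravitationally lowest duct point
#'
#' Returns the arc coordinate (degrees from the ampulla end) of the lowest
#' point of the duct circle at orientation `beta_deg`.  The value is
#' deliberately not clamped to the duct span: equilibria outside `[0, span]`
#' mean the particle slides onto an absorbing end.  At upright orientation
#' with the ampulla 32 deg below the horizontal the lowest point lies 58 deg
#' from the ampulla, the particle's resting position before a maneuver.
#'
#' @param canal A [canal_geometry()].
#' @param beta_deg Canal orientation (degrees; 0 = upright, positive in the
#'   first-movement direction).
#' @return Arc coordinate psi_bottom in degrees (possibly outside the span).
#' @examples
#' lowest_point(canal_geometry(), 0)    # 58
#' lowest_point(canal_geometry(), 110)  # 168
#' @export
lowest_point <- function(canal, beta_deg) {
  stopifnot(inherits(canal, "canal_geometry"))
  (90 - canal$upright_ampulla_elevation_deg) + beta_deg
}

# Effective lowest point and settling-speed factor for a given effective
# gravity vector (lab frame) and orientation.  gamma is the vector's polar
# angle; plain gravity (0,-g) has gamma = -90 deg and reproduces
# psi_bottom = (90 - elev) + beta.
.lowest_point_eff <- function(elev_deg, beta_deg, g_eff) {
  gamma_deg <- .rad2deg(atan2(g_eff[2], g_eff[1]))
  -elev_deg - gamma_deg + beta_deg
}

#' Instantaneous slip rate of the canalith
#'
#' Right-hand side of the transport equation: the rate of change of the arc
#' coordinate psi under the effective gravity at time `t` of the maneuver.
#' Zero at the (stable) effective low point and at the antipodal (unstable)
#' apex; maximal in magnitude 90 deg away from the low point.
#'
#' @param psi_deg Arc position of the particle (degrees from the ampulla).
#' @param t Time within the trace span (s).
#' @param trace An [build_trace()] orientation trace.
#' @param canal A [canal_geometry()].
#' @param materials A [material_spec()].
#' @param drag_correction Wall-drag correction lambda (>= 1).
#' @param pivot_offset Pivot offset L (m); defaults to the trace's value.
#' @param gravity Gravitational acceleration (m/s^2).
#' @return d(psi)/dt in degrees/s.
#' @export
slip_rate <- function(psi_deg, t, trace, canal, materials,
                      drag_correction = 1, pivot_offset = NULL,
                      gravity = .canalith_gravity) {
  stopifnot(inherits(trace, "orientation_trace"),
            inherits(canal, "canal_geometry"))
  if (is.null(pivot_offset)) pivot_offset <- trace$spec$pivot_offset_m
  ev <- .eval_segments(trace$segments, t)
  vs_deg <- .rad2deg(settling_velocity(materials, drag_correction, gravity) /
                       canal$major_radius)
  g_eff <- .effective_gravity(.deg2rad(ev$beta_deg),
                              .deg2rad(ev$omega_deg_s),
                              .deg2rad(ev$accel_deg_s2),
                              pivot_offset, gravity)
  psi_b <- .lowest_point_eff(canal$upright_ampulla_elevation_deg,
                             ev$beta_deg, g_eff)
  gfac <- sqrt(sum(g_eff^2)) / gravity
  -vs_deg * gfac * sin(.deg2rad(psi_deg - psi_b))
}

#' Integrate the canalith trajectory over a maneuver
#'
#' Solves the overdamped transport equation along the orientation trace with
#' adaptive integration (lsodar) and event detection at the absorbing duct
#' ends.  Integration proceeds segment by segment, so velocity
#' discontinuities at phase boundaries are handled exactly.  If at the start
#' of the final phase the particle sits exactly on the unstable apex
#' (antipode of the low point), the tie resolves towards the ampulla side: a
#' fully settled particle after an alpha_plus = 0 maneuver ends exactly on
#' the apex and must classify as a failure.
#'
#' @param canal A [canal_geometry()].
#' @param materials A [material_spec()].
#' @param drag_correction Wall-drag correction lambda (>= 1).
#' @param trace An [build_trace()] or [sample_manual_trace()] orientation
#'   trace.
#' @param psi0_deg Initial arc position (degrees); defaults to the lowest
#'   point at the trace's initial orientation (the settled pre-maneuver
#'   position).
#' @param rtol,atol Relative and absolute integration tolerances (degrees
#'   for `atol`).
#' @param sample_step Output sampling step (s).
#' @param gravity Gravitational acceleration (m/s^2).
#' @return An object of class `canalith_trajectory`: list with `data`
#'   (columns `time_s`, `psi_deg`, `beta_deg`, `phase`, `status`), terminal
#'   `status` (`"in_duct"`, `"in_ampulla"`, `"in_utricle"`), `absorbed_at_s`,
#'   and `end_of_phase` (named arc positions at each phase end).
#' @examples
#' tr <- build_trace(maneuver_spec(20, 135, 45), sample_step = 0.01)
#' traj <- simulate_maneuver(canal_geometry(), model_materials(), 4, tr)
#' traj$status
#' @export
simulate_maneuver <- function(canal, materials, drag_correction, trace,
                              psi0_deg = NULL, rtol = 1e-8, atol = 1e-5,
                              sample_step = 0.02,
                              gravity = .canalith_gravity) {
  stopifnot(inherits(canal, "canal_geometry"),
            inherits(materials, "material_spec"),
            inherits(trace, "orientation_trace"))
  span <- canal$duct_span_deg
  elev <- canal$upright_ampulla_elevation_deg
  L <- trace$spec$pivot_offset_m
  if (is.null(psi0_deg)) {
    psi0_deg <- lowest_point(canal, trace$segments$beta0_deg[1L])
  }
  if (psi0_deg < 0 || psi0_deg > span) {
    stop("invalid parameter `psi0_deg`: must lie within [0, ", span, "]",
         call. = FALSE)
  }
  vs_deg <- .rad2deg(settling_velocity(materials, drag_correction, gravity) /
                       canal$major_radius)

  rhs <- function(t, y, p) {
    dt <- t - p$t0
    beta <- p$beta0 + p$omega0 * dt + 0.5 * p$accel * dt^2
    if (p$moving) {
      omega_r <- .deg2rad(p$omega0 + p$accel * dt)
      g_eff <- .effective_gravity(.deg2rad(beta), omega_r,
                                  p$accel_rad, p$L, p$g)
      psi_b <- -p$elev - .rad2deg(atan2(g_eff[2], g_eff[1])) + beta
      gfac <- sqrt(g_eff[1]^2 + g_eff[2]^2) / p$g
    } else {
      psi_b <- (90 - p$elev) + beta
      gfac <- 1
    }
    list(-p$vs * gfac * sin(.deg2rad(y[1] - psi_b)))
  }
  rootfun <- function(t, y, p) c(y[1], p$span - y[1])

  segs <- trace$segments
  psi <- psi0_deg
  status <- "in_duct"
  absorbed_at <- NA_real_
  rows <- vector("list", nrow(segs))
  end_of_phase <- c()

  for (k in seq_len(nrow(segs))) {
    sg <- segs[k, ]
    # apex tie-break at the start of the final settling phase
    if (sg$phase == "final") {
      apex <- lowest_point(canal, sg$beta0_deg) + 180
      if (abs(psi - apex) < 1e-9) psi <- apex - 1e-9
    }
    p <- list(t0 = sg$t0, beta0 = sg$beta0_deg, omega0 = sg$omega0_deg_s,
              accel = sg$accel_deg_s2, accel_rad = .deg2rad(sg$accel_deg_s2),
              moving = L > 0 && (sg$omega0_deg_s != 0 ||
                                   sg$accel_deg_s2 != 0),
              L = L, g = gravity, elev = elev, vs = vs_deg, span = span)
    times <- seq(sg$t0, sg$t1, by = sample_step)
    if (times[length(times)] < sg$t1 - 1e-12) times <- c(times, sg$t1)
    if (length(times) < 2L) times <- c(sg$t0, sg$t1)
    out <- deSolve::ode(y = c(psi = psi), times = times, func = rhs,
                        parms = p, method = "lsodar", rootfunc = rootfun,
                        rtol = rtol, atol = atol)
    ot <- out[, 1L]
    op <- out[, 2L]
    rows[[k]] <- data.frame(time_s = ot, psi_deg = op,
                            phase = sg$phase, stringsAsFactors = FALSE)
    psi <- op[length(op)]
    troot <- attr(out, "troot")
    hit_root <- (!is.null(troot) && length(troot) > 0L) ||
      ot[length(ot)] < sg$t1 - 1e-8 || psi <= atol || psi >= span - atol
    if (hit_root) {
      absorbed_at <- ot[length(ot)]
      status <- if (abs(psi) < abs(span - psi)) "in_ampulla" else "in_utricle"
      psi <- if (status == "in_ampulla") 0 else span
      end_of_phase[sg$phase] <- psi
      break
    }
    end_of_phase[sg$phase] <- psi
  }

  data <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  data <- data[!duplicated(data$time_s), , drop = FALSE]
  data$beta_deg <- .eval_segments(segs, data$time_s)$beta_deg
  data$status <- "in_duct"
  if (status != "in_duct") data$status[nrow(data)] <- status
  rownames(data) <- NULL
  structure(
    list(data = data[, c("time_s", "psi_deg", "beta_deg", "phase", "status")],
         status = status, absorbed_at_s = absorbed_at,
         end_of_phase = end_of_phase,
         psi0_deg = psi0_deg, drag_correction = drag_correction,
         canal = canal, materials = materials, trace_total_s = trace$total_s),
    class = "canalith_trajectory")
}

#' @export
print.canalith_trajectory <- function(x, ...) {
  cat("<canalith_trajectory>", x$status,
      if (!is.na(x$absorbed_at_s)) paste("at t =", format(x$absorbed_at_s),
                                         "s"),
      "\n end of phase:",
      paste(names(x$end_of_phase), round(x$end_of_phase, 2), sep = "=",
            collapse = ", "), "deg\n")
  invisible(x)
}

#' @export
as.data.frame.canalith_trajectory <- function(x, ...) x$data

#' Classify a maneuver outcome from a trajectory
#'
#' A maneuver is a `"success"` if the particle settled in the utricle, a
#' `"failure"` if it settled in the ampulla, and `"undecided"` if it was
#' still inside the duct at the end of the observation window (extend
#' `final_observation_s` in that case).
#'
#' @param trajectory A [simulate_maneuver()] result.
#' @return One of `"success"`, `"failure"`, `"undecided"`.
#' @export
classify_outcome <- function(trajectory) {
  stopifnot(inherits(trajectory, "canalith_trajectory"))
  switch(trajectory$status,
         in_utricle = "success",
         in_ampulla = "failure",
         "undecided")
}

#' Plot a canalith trajectory
#'
#' Arc position against time with phase boundaries marked; the dashed lines
#' are the absorbing duct ends (ampulla at 0, utricle at the duct span).
#'
#' @param x A `canalith_trajectory`.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.canalith_trajectory <- function(x, ...) {
  d <- x$data
  graphics::plot(d$time_s, d$psi_deg, type = "l", xlab = "time (s)",
                 ylab = "arc position from ampulla (deg)", ...)
  graphics::abline(h = c(0, x$canal$duct_span_deg), lty = 2, col = "grey40")
  bounds <- tapply(d$time_s, d$phase, max)
  graphics::abline(v = bounds, lty = 3, col = "grey70")
  invisible(x)
}
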