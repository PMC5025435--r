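test_that("movement phases have the parametrized sweeps and durations", {
  tr <- build_trace(maneuver_spec(20, 90, 5, final_observation_s = 2),
                    sample_step = 0.01)
  segs <- tr$segments
  m1 <- segs[segs$phase == "move1", ]
  m2 <- segs[segs$phase == "move2", ]
  expect_equal(m1$t1 - m1$t0, 110 / 90)
  # second movement sweeps 180 + 2*alpha_plus degrees
  expect_equal(sum(m2$t1 - m2$t0) * 90, 220)
  # orientation endpoints of the two movements
  ev <- kinematics_at(tr, c(max(m1$t1), max(m2$t1)))
  expect_equal(ev$beta_deg, c(110, -110))

  # recommended velocity: 90 deg in 2/3 s (~0.66 s), 180 deg in ~1.33 s
  tr135 <- build_trace(maneuver_spec(0, 135, 1, final_observation_s = 1),
                       sample_step = 0.01)
  d1 <- with(tr135$segments[tr135$segments$phase == "move1", ], t1 - t0)
  expect_equal(d1, 2 / 3)
  expect_lte(abs(d1 - 0.66), 0.01)
  expect_equal(180 / 135, 4 / 3)
})

test_that("total maneuver time is the sum of the phase durations", {
  v <- 120
  tr <- build_trace(maneuver_spec(0, v, 0, final_observation_s = 1e-6),
                    sample_step = 0.01)
  # movement sweeps at alpha_plus = 0 are 90 and 180 degrees
  expect_equal(tr$total_s, (90 + 180) / v, tolerance = 1e-5)
})

test_that("angular velocity integrates to the orientation change", {
  tr <- build_trace(maneuver_spec(15, 135, 3, final_observation_s = 1),
                    sample_step = 0.002)
  s <- tr$samples
  # whole trace: from upright to -(90 + alpha_plus)
  net <- sum(diff(s$time_s) * (head(s$omega_deg_s, -1) +
                                 tail(s$omega_deg_s, -1)) / 2)
  expect_equal(net, -105, tolerance = 0.1)
  # movement 2 alone sweeps -(180 + 2*alpha_plus)
  m2 <- s[s$phase == "move2", ]
  net2 <- sum(diff(m2$time_s) * (head(m2$omega_deg_s, -1) +
                                   tail(m2$omega_deg_s, -1)) / 2)
  expect_equal(net2, -210, tolerance = 0.5)
  # no rotation while resting or observing
  expect_true(all(s$omega_deg_s[s$phase %in% c("rest", "final")] == 0))
})

test_that("doubling the velocity halves movement durations only", {
  dur <- function(v) {
    segs <- build_trace(maneuver_spec(20, v, 7, final_observation_s = 2),
                        sample_step = 0.01)$segments
    tapply(segs$t1 - segs$t0, segs$phase, sum)
  }
  d90 <- dur(90)
  d180 <- dur(180)
  expect_equal(as.numeric(d90[c("move1", "move2")] /
                            d180[c("move1", "move2")]), c(2, 2))
  expect_equal(d90[["rest"]], d180[["rest"]])
  expect_equal(d90[["final"]], d180[["final"]])
})

test_that("trapezoidal ramps preserve the swept angles", {
  for (ramp in c(0.1, 0.3)) {
    tr <- build_trace(maneuver_spec(20, 135, 2, final_observation_s = 1,
                                    ramp_time_s = ramp), sample_step = 0.005)
    s <- tr$samples
    expect_equal(max(s$beta_deg), 110, tolerance = 1e-8)
    expect_equal(min(s$beta_deg), -110, tolerance = 1e-8)
    # orientation stays continuous (no jumps beyond one step at max speed)
    expect_lt(max(abs(diff(s$beta_deg))), 135 * 0.005 + 1e-6)
    # plateau runs at the nominal velocity
    expect_equal(max(abs(s$omega_deg_s)), 135)
  }
  expect_error(build_trace(maneuver_spec(20, 135, 2, ramp_time_s = 2)),
               "ramp")
})

test_that("lever-arm kinematics produce the inertial terms", {
  tr <- build_trace(maneuver_spec(20, 90, 4, final_observation_s = 2,
                                  pivot_offset_m = 0.72),
                    sample_step = 0.01)
  # during rest: no rotation, no inertial acceleration
  k_rest <- kinematics_at(tr, 110 / 90 + 1)
  expect_equal(k_rest$omega_deg_s, 0)
  expect_equal(k_rest$inertial_centrifugal_m_s2, 0)
  expect_equal(k_rest$inertial_tangential_m_s2, 0)
  # plateau at 90 deg/s: centrifugal term (pi/2)^2 * 0.72
  k_move <- kinematics_at(tr, 0.5)
  expect_equal(k_move$inertial_centrifugal_m_s2, (pi / 2)^2 * 0.72,
               tolerance = 1e-10)
  # stepper setup: pivot at the canal centre, no inertial terms anywhere
  k0 <- kinematics_at(tr, c(0.5, 2, 4), pivot_offset = 0)
  expect_true(all(k0$inertial_centrifugal_m_s2 == 0))
  expect_true(all(k0$inertial_tangential_m_s2 == 0))
  expect_error(kinematics_at(tr, tr$total_s + 1), "out of range")
})

test_that("maneuver specification rejects invalid parameters", {
  expect_error(maneuver_spec(20, 0, 5), "maneuver_velocity_deg_s")
  expect_error(maneuver_spec(-5, 90, 5), "extension_angle_deg")
  expect_error(maneuver_spec(50, 90, 5), "extension_angle_deg")
  expect_error(build_trace(maneuver_spec(20, 90, 5), sample_step = 0.5),
               "sample_step")
})
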