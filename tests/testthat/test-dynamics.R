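test_that("the lowest duct point tracks the canal orientation", {
  canal <- canal_geometry()
  # upright, ampulla 32 deg below horizontal: low point 58 deg from ampulla
  expect_equal(lowest_point(canal, 0), 58)
  # after the first movement by 90 + 20 deg
  expect_equal(lowest_point(canal, 110), 168)
  # unclamped outside the duct span: absorption is the integrator's business
  expect_equal(lowest_point(canal, -110), -52)
  expect_lt(lowest_point(canal, -110), 0)
  # elevation dependence
  expect_equal(lowest_point(canal_geometry(upright_ampulla_elevation_deg = 0),
                            0), 90)
})

test_that("slip rate vanishes at equilibria and peaks at 90 degrees", {
  canal <- canal_geometry()
  mat <- model_materials()
  tr <- build_trace(maneuver_spec(20, 135, 10, final_observation_s = 5),
                    sample_step = 0.01)
  t_rest <- 110 / 135 + 5  # mid-rest, beta = 110, low point at 168
  vs_deg <- settling_velocity(mat) / canal$major_radius * 180 / pi
  expect_equal(slip_rate(168, t_rest, tr, canal, mat), 0)
  expect_equal(slip_rate(168 - 90, t_rest, tr, canal, mat), vs_deg,
               tolerance = 1e-10)
  expect_equal(slip_rate(168 + 90, t_rest, tr, canal, mat), -vs_deg,
               tolerance = 1e-10)
  # unstable apex equilibrium
  expect_equal(slip_rate(168 - 180, t_rest, tr, canal, mat), 0,
               tolerance = 1e-12)
  # drag correction scales the rate down
  expect_equal(slip_rate(100, t_rest, tr, canal, mat, drag_correction = 4),
               slip_rate(100, t_rest, tr, canal, mat) / 4)
})

test_that("resting-time length separates failure from success", {
  canal <- canal_geometry()
  mat <- model_materials()
  lam <- 4
  short <- simulate_maneuver(canal, mat, lam,
                             build_trace(maneuver_spec(20, 135, 5),
                                         sample_step = 0.01))
  long <- simulate_maneuver(canal, mat, lam,
                            build_trace(maneuver_spec(20, 135, 45),
                                        sample_step = 0.01))
  expect_identical(short$status, "in_ampulla")
  expect_identical(classify_outcome(short), "failure")
  expect_identical(long$status, "in_utricle")
  expect_identical(classify_outcome(long), "success")
  # absorbed trajectories end exactly on the duct ends
  expect_equal(short$data$psi_deg[nrow(short$data)], 0)
  expect_equal(long$data$psi_deg[nrow(long$data)], canal$duct_span_deg)
  expect_lt(short$absorbed_at_s, short$trace_total_s)
})

test_that("settling during rest is monotone towards the low point", {
  canal <- canal_geometry()
  mat <- model_materials()
  traj <- simulate_maneuver(canal, mat, 4,
                            build_trace(maneuver_spec(20, 135, 30),
                                        sample_step = 0.01))
  rest <- traj$data[traj$data$phase == "rest", ]
  gap <- abs(rest$psi_deg - 168)
  expect_true(all(diff(gap) <= 1e-9))
  # approaches the equilibrium without overshooting
  expect_true(all(rest$psi_deg <= 168 + 1e-9))
})

test_that("end-of-phase positions are robust to integrator tolerance", {
  canal <- canal_geometry()
  mat <- model_materials()
  tr <- build_trace(maneuver_spec(20, 135, 20), sample_step = 0.01)
  a <- simulate_maneuver(canal, mat, 4, tr, rtol = 1e-8, atol = 1e-5)
  b <- simulate_maneuver(canal, mat, 4, tr, rtol = 1e-9, atol = 1e-6)
  common <- intersect(names(a$end_of_phase), names(b$end_of_phase))
  expect_lt(max(abs(a$end_of_phase[common] - b$end_of_phase[common])), 0.01)
  expect_identical(a$status, b$status)
})

test_that("a particle still inside the duct classifies as undecided", {
  canal <- canal_geometry()
  mat <- model_materials()
  # heavy drag and a short observation window: the particle cannot reach
  # either end before the trace runs out
  tr <- build_trace(maneuver_spec(20, 135, 8, final_observation_s = 0.5),
                    sample_step = 0.01)
  traj <- simulate_maneuver(canal, mat, 20, tr)
  expect_identical(traj$status, "in_duct")
  expect_identical(classify_outcome(traj), "undecided")
})

test_that("initial position must lie inside the duct", {
  canal <- canal_geometry()
  tr <- build_trace(maneuver_spec(20, 135, 5), sample_step = 0.01)
  expect_error(simulate_maneuver(canal, model_materials(), 4, tr,
                                 psi0_deg = -5), "psi0_deg")
  expect_error(simulate_maneuver(canal, model_materials(), 4, tr,
                                 psi0_deg = 300), "psi0_deg")
  # default start: settled at the upright low point
  traj <- simulate_maneuver(canal, model_materials(), 4, tr)
  expect_equal(traj$psi0_deg, 58)
})

test_that("lever-arm inertia perturbs the trajectory only while moving", {
  canal <- canal_geometry()
  mat <- model_materials()
  spec0 <- maneuver_spec(20, 135, 15, pivot_offset_m = 0)
  specL <- maneuver_spec(20, 135, 15, pivot_offset_m = 0.72)
  t0 <- simulate_maneuver(canal, mat, 4, build_trace(spec0,
                                                     sample_step = 0.01))
  tL <- simulate_maneuver(canal, mat, 4, build_trace(specL,
                                                     sample_step = 0.01))
  # the pivot offset changes the end-of-movement positions measurably but
  # not drastically
  expect_false(isTRUE(all.equal(t0$end_of_phase[["move1"]],
                                tL$end_of_phase[["move1"]])))
  expect_lt(abs(t0$end_of_phase[["move1"]] - tL$end_of_phase[["move1"]]), 10)
})
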