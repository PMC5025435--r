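test_that("deterministic critical-time scan finds a monotone boundary", {
  cfg <- stepper_config(20, 135, lambda = 4)
  res <- find_critical_time(cfg)
  expect_s3_class(res, "critical_time_result")
  expect_false(is.na(res$critical_time_s))
  # refined boundary sits within one scan step below the scan value
  expect_lte(res$refined_s, res$critical_time_s)
  expect_gte(res$refined_s, res$critical_time_s - 1)
  # monotonicity: everything scanned below the critical time failed, and a
  # longer rest also succeeds
  hist <- res$history
  below <- hist$resting_time_s < res$critical_time_s &
    hist$resting_time_s >= 5
  expect_true(all(hist$outcome[below] == "failure"))
  expect_identical(canalith:::.run_outcome(cfg, res$critical_time_s + 5),
                   "success")
})

test_that("no-success configurations return none via the scan bound", {
  cfg <- stepper_config(0, 135, lambda = 4)
  res <- find_critical_time(cfg, max = 120)
  expect_true(is.na(res$critical_time_s))
  expect_identical(res$history$outcome[1], "failure")
  expect_equal(res$history$resting_time_s[1], 120)
})

test_that("critical time increases strictly with the drag correction", {
  crit <- function(lambda) {
    canalith:::.critical_time_bisect(stepper_config(30, 90, lambda),
                                     resolution = 0.05)
  }
  c2 <- crit(2)
  c4 <- crit(4)
  c8 <- crit(8)
  expect_lt(c2, c4)
  expect_lt(c4, c8)
})

test_that("drag calibration hits its target cell", {
  lam <- calibrated_lambda()
  expect_gt(lam, 1)
  expect_lt(lam, 20)
  achieved <- canalith:::.critical_time_bisect(stepper_config(30, 90, lam),
                                               resolution = 0.02)
  expect_equal(achieved, 9, tolerance = 0.02)
  # free Stokes drag settles far too quickly to need a 9 s rest
  free <- canalith:::.critical_time_bisect(stepper_config(30, 90, 1),
                                           resolution = 0.05)
  expect_lt(free, 9)
})

test_that("calibration fails cleanly without a bracketing sign change", {
  cfg <- stepper_config(30, 90, NA)
  expect_error(calibrate_drag(cfg, target_critical_time_s = 0.5),
               "bracketing")
})

test_that("grid replication labels unrepositionable cells as NA", {
  cells <- data.frame(setup = "stepper",
                      particle_diameter_um = 250,
                      extension_angle_deg = c(0, 30),
                      maneuver_velocity_deg_s = 135,
                      stringsAsFactors = FALSE)
  out <- replicate_experiment_grid(bench_canal(), bench_materials(), 4,
                                   cells, max = 120)
  expect_true(is.na(out$critical_time_s[1]))
  expect_false(is.na(out$critical_time_s[2]))
  expect_named(out, c(names(cells), "critical_time_s", "refined_s"))
  expect_error(
    replicate_experiment_grid(bench_canal(), bench_materials(), 4,
                              data.frame(setup = "stepper")),
    "missing column")
})

test_that("settling slows down with drag and with smaller particles", {
  fast <- settling_time_after_first_movement(stepper_config(20, 90, 1))
  slow <- settling_time_after_first_movement(stepper_config(20, 90, 4))
  small <- settling_time_after_first_movement(
    stepper_config(20, 90, 4, particle_diameter_um = 180))
  expect_lt(fast, slow)
  expect_lt(slow, small)
  # the size effect follows the cross-section ratio closely
  expect_equal(small / slow, (250 / 180)^2, tolerance = 0.05)
})

test_that("recommendations scale the resting time by the cross-section", {
  rec <- recommend_maneuver(25, reference_critical_time_s = 11)
  expect_equal(rec$multiplier, 4)
  expect_equal(rec$resting_time_raw_s, 44)
  expect_equal(rec$resting_time_s, 45)
  expect_equal(rec$first_movement_deg, 110)
  expect_equal(rec$second_movement_deg, 220)
  expect_equal(rec$velocity_deg_s, 135)
  # slower maneuvers: scale the low-velocity reference instead
  rec90 <- recommend_maneuver(25, reference_critical_time_s = 16,
                              velocity_deg_s = 90)
  expect_equal(rec90$resting_time_raw_s, 64)
  expect_equal(rec90$resting_time_s, 65)
  expect_warning(recommend_maneuver(10, reference_critical_time_s = 11),
                 "not very relevant")
  expect_error(recommend_maneuver(60, reference_critical_time_s = 11),
               "above 50")
})
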