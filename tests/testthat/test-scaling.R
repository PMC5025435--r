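test_that("viscosity factor follows the f^2 similarity rule", {
  expect_equal(required_viscosity_factor(5), 25)
  expect_equal(required_viscosity_factor(1), 1)
  expect_equal(required_viscosity_factor(3), 9)
  expect_error(required_viscosity_factor(0), "must be positive")
  expect_error(required_viscosity_factor(-2), "must be positive")
  expect_error(required_viscosity_factor(0.5), ">= 1")
})

test_that("density-ratio rule is affine in the human ratio and anchored", {
  expect_equal(required_density_ratio(5, 2.7), 9.5)
  expect_equal(required_density_ratio(2, 2), 3)
  # neutrally buoyant fixed point for any scaling factor
  for (f in c(1, 2, 5, 10)) expect_equal(required_density_ratio(f, 1), 1)
  # affine in r, slope f, identity at f = 1
  f <- 3.7
  r <- c(1, 1.5, 2.2, 3)
  vals <- vapply(r, function(x) required_density_ratio(f, x), 0)
  expect_equal(diff(vals) / diff(r), rep(f, 3))
  expect_equal(vapply(r, function(x) required_density_ratio(1, x), 0), r)
  expect_error(required_density_ratio(5, 0.9), ">= 1")
})

test_that("unscaling the bench model reproduces the human parameter column", {
  un <- unscale_model(model_materials(), scaling_spec(),
                      canal = canal_geometry())
  expect_equal(un$canal$major_radius, 3.2e-3)
  expect_equal(un$canal$duct_radius, 0.15e-3)
  expect_equal(un$materials$fluid_kinematic_viscosity, 1.08e-6)
  expect_equal(un$materials$fluid_density, 1000)
  expect_equal(un$materials$particle_diameter, 50e-6)
  # 1000 * (1 + (7800/945 - 1)/5) = 2450.79...; printed to 3 s.f. as 2450
  expect_equal(un$materials$particle_density, 2450.7937, tolerance = 1e-6)
  expect_equal(signif(un$materials$particle_density, 3), 2450)
  expect_identical(un$materials$regime, "human")

  small <- unscale_model(model_materials(180e-6))
  expect_equal(small$particle_diameter, 36e-6)

  expect_error(unscale_model(human_materials()), "scaled_model")
})

test_that("unscale/rescale round trip recovers the bench spec exactly", {
  model <- model_materials()
  back <- rescale_model(unscale_model(model), scaling_spec(),
                        model_fluid_density = model$fluid_density)
  expect_equal(back$fluid_kinematic_viscosity,
               model$fluid_kinematic_viscosity)
  expect_equal(back$particle_diameter, model$particle_diameter)
  expect_equal(back$particle_density, model$particle_density)
  expect_equal(back$fluid_density, model$fluid_density)
})

test_that("settling velocity follows Stokes' law in D^2", {
  # hand evaluation: (7800-945)*9.81*(250e-6)^2 / (18*945*27e-6)
  expect_equal(settling_velocity(model_materials()), 9.1514e-3,
               tolerance = 1e-4)
  # neutral buoyancy
  neutral <- material_spec(27e-6, 945, 250e-6, 945)
  expect_equal(settling_velocity(neutral), 0)
  # exactly quadratic in diameter
  v1 <- settling_velocity(model_materials(125e-6))
  v2 <- settling_velocity(model_materials(250e-6))
  expect_equal(v2 / v1, 4)
  # cross-section ratio between the two bench particle sizes
  v180 <- settling_velocity(model_materials(180e-6))
  expect_equal(v2 / v180, (250 / 180)^2)
  # drag correction slows settling proportionally
  expect_equal(settling_velocity(model_materials(), drag_correction = 4),
               settling_velocity(model_materials()) / 4)
  expect_error(settling_velocity(model_materials(), drag_correction = 0.5),
               ">= 1")
})

test_that("bench particles settle slower than human by the predicted ratio", {
  ratio <- settling_slowdown(model_materials(), human_materials())
  expect_equal(ratio, 1.2656, tolerance = 1e-3)
  # perfectly scaled pairing has no slowdown
  perfect <- rescale_model(human_materials(), scaling_spec(),
                           model_fluid_density = 945)
  expect_equal(settling_slowdown(perfect, human_materials()), 1)
  expect_error(settling_slowdown(model_materials(), human_materials(40e-6)),
               "unpaired")
})

test_that("material and scaling constructors validate their inputs", {
  expect_error(material_spec(-1e-6, 1000, 50e-6, 2700),
               "fluid_kinematic_viscosity")
  expect_error(material_spec(1e-6, 1000, 50e-6, 900), "particle_density")
  expect_error(scaling_spec(geometric_factor = 0.5), "geometric_factor")
})
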