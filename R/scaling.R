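# Dynamic-similarity scaling between the five-fold scaled bench model of the
# semicircular canal (SCC) and the human organ, plus the Stokes settling
# relations that drive all particle-size arguments.
#
# The bench model is geometrically scaled by a factor f.  Matching the settling
# dynamics on the same time base requires the model fluid's kinematic viscosity
# to be f^2 times larger than endolymph viscosity and the particle-to-fluid
# density ratio to satisfy 1 + f*(rho_p/rho - 1), where rho_p/rho is the
# human otoconia-to-endolymph density ratio.

#' Material specification for a fluid/particle pairing
#'
#' Bundles the fluid (endolymph or its scaled analogue) and the particle
#' (otoconium or its scaled analogue) properties used by the settling model.
#' All values are SI.
#'
#' @param fluid_kinematic_viscosity Kinematic viscosity of the fluid (m^2/s).
#' @param fluid_density Fluid density (kg/m^3).
#' @param particle_diameter Particle diameter (m).
#' @param particle_density Particle density (kg/m^3); must be at least the
#'   fluid density (a buoyant particle never settles).
#' @param regime `"scaled_model"` for the bench model or `"human"`.
#' @return An object of class `material_spec`.
#' @seealso [model_materials()], [human_materials()], [settling_velocity()]
#' @export
material_spec <- function(fluid_kinematic_viscosity, fluid_density,
                          particle_diameter, particle_density,
                          regime = c("scaled_model", "human")) {
  regime <- match.arg(regime)
  .check_positive(fluid_kinematic_viscosity, "fluid_kinematic_viscosity")
  .check_positive(fluid_density, "fluid_density")
  .check_positive(particle_diameter, "particle_diameter")
  .check_positive(particle_density, "particle_density")
  if (particle_density < fluid_density) {
    stop("invalid parameter `particle_density`: must be >= fluid_density ",
         "for a settling particle", call. = FALSE)
  }
  structure(
    list(fluid_kinematic_viscosity = fluid_kinematic_viscosity,
         fluid_density = fluid_density,
         particle_diameter = particle_diameter,
         particle_density = particle_density,
         regime = regime),
    class = "material_spec")
}

#' @export
print.material_spec <- function(x, ...) {
  cat("<material_spec> regime:", x$regime, "\n",
      " fluid: nu =", format(x$fluid_kinematic_viscosity), "m^2/s, rho =",
      x$fluid_density, "kg/m^3\n",
      " particle: D =", format(x$particle_diameter * 1e6), "um, rho_p =",
      x$particle_density, "kg/m^3\n")
  invisible(x)
}

#' Bench-model and human material pairings
#'
#' `model_materials()` returns the scaled bench model pairing: a viscous
#' endolymph analogue (nu = 27e-6 m^2/s, rho = 945 kg/m^3) with steel
#' microspheres (rho_p = 7800 kg/m^3, D = 180 or 250 um).
#' `human_materials()` returns the physiological reference: endolymph
#' (nu = 1e-6 m^2/s, rho = 1000 kg/m^3) with calcite otoconia
#' (rho_p = 2700 kg/m^3).
#'
#' @param particle_diameter Particle diameter in metres (default 250 um for
#'   the model, 50 um for the human reference).
#' @return A [material_spec()].
#' @export
model_materials <- function(particle_diameter = 250e-6) {
  material_spec(27e-6, 945, particle_diameter, 7800, "scaled_model")
}

#' @rdname model_materials
#' @export
human_materials <- function(particle_diameter = 50e-6) {
  material_spec(1e-6, 1000, particle_diameter, 2700, "human")
}

#' Geometric scaling specification
#'
#' @param geometric_factor Geometric scaling factor f (>= 1); lengths in the
#'   bench model are f times the human lengths.
#' @param reference_endolymph_density Human endolymph density (kg/m^3).
#' @param reference_otoconia_density Human otoconia density (kg/m^3).
#' @return An object of class `scaling_spec`.
#' @export
scaling_spec <- function(geometric_factor = 5,
                         reference_endolymph_density = 1000,
                         reference_otoconia_density = 2700) {
  if (!is.numeric(geometric_factor) || length(geometric_factor) != 1L ||
      is.na(geometric_factor) || geometric_factor < 1) {
    stop("invalid parameter `geometric_factor`: must be >= 1", call. = FALSE)
  }
  .check_positive(reference_endolymph_density, "reference_endolymph_density")
  .check_positive(reference_otoconia_density, "reference_otoconia_density")
  structure(
    list(geometric_factor = geometric_factor,
         reference_endolymph_density = reference_endolymph_density,
         reference_otoconia_density = reference_otoconia_density),
    class = "scaling_spec")
}

#' Viscosity factor required by dynamic similarity
#'
#' For a model scaled geometrically by f, settling dynamics on the original
#' time base require the model fluid's kinematic viscosity to be f^2 times
#' the endolymph viscosity.
#'
#' @param f Geometric scaling factor (>= 1).
#' @return The dimensionless viscosity multiplier f^2.
#' @examples
#' required_viscosity_factor(5)  # 25
#' @export
required_viscosity_factor <- function(f) {
  if (!is.numeric(f) || length(f) != 1L || is.na(f) || f <= 0) {
    stop("invalid parameter `f`: must be positive", call. = FALSE)
  }
  if (f < 1) stop("invalid parameter `f`: must be >= 1", call. = FALSE)
  f^2
}

#' Particle-to-fluid density ratio required by dynamic similarity
#'
#' @param f Geometric scaling factor (>= 1).
#' @param human_ratio Otoconia-to-endolymph density ratio (>= 1);
#'   approximately 2.7 for calcite otoconia in endolymph.
#' @return The required model density ratio `1 + f * (human_ratio - 1)`.
#' @examples
#' required_density_ratio(5, 2.7)  # 9.5
#' @export
required_density_ratio <- function(f, human_ratio) {
  if (!is.numeric(f) || length(f) != 1L || is.na(f) || f < 1) {
    stop("invalid parameter `f`: must be >= 1", call. = FALSE)
  }
  if (!is.numeric(human_ratio) || length(human_ratio) != 1L ||
      is.na(human_ratio) || human_ratio < 1) {
    stop("invalid parameter `human_ratio`: must be >= 1", call. = FALSE)
  }
  1 + f * (human_ratio - 1)
}

#' Map a scaled bench model onto the corresponding human canal
#'
#' Inverts the dynamic-similarity scaling: lengths are divided by f, the
#' kinematic viscosity by f^2, the fluid density is replaced by the reference
#' endolymph density, and the particle density follows from inverting the
#' density-ratio rule,
#' `rho_p_human = rho_ref * (1 + (rho_p_model/rho_model - 1) / f)`.
#'
#' @param materials A `material_spec` with regime `"scaled_model"`.
#' @param scaling A [scaling_spec()].
#' @param canal Optional [canal_geometry()] of the bench model; its lengths
#'   are divided by f.
#' @return If `canal` is `NULL`, a human-regime `material_spec`; otherwise a
#'   list with elements `materials` and `canal`.
#' @examples
#' unscale_model(model_materials(), scaling_spec())
#' @export
unscale_model <- function(materials, scaling = scaling_spec(), canal = NULL) {
  stopifnot(inherits(materials, "material_spec"),
            inherits(scaling, "scaling_spec"))
  if (materials$regime != "scaled_model") {
    stop("invalid parameter `materials`: regime must be \"scaled_model\"",
         call. = FALSE)
  }
  f <- scaling$geometric_factor
  ratio_model <- materials$particle_density / materials$fluid_density
  human <- material_spec(
    fluid_kinematic_viscosity = materials$fluid_kinematic_viscosity / f^2,
    fluid_density = scaling$reference_endolymph_density,
    particle_diameter = materials$particle_diameter / f,
    particle_density = scaling$reference_endolymph_density *
      (1 + (ratio_model - 1) / f),
    regime = "human")
  if (is.null(canal)) return(human)
  stopifnot(inherits(canal, "canal_geometry"))
  list(materials = human,
       canal = canal_geometry(
         major_radius = canal$major_radius / f,
         duct_radius = canal$duct_radius / f,
         duct_span_deg = canal$duct_span_deg,
         upright_ampulla_elevation_deg = canal$upright_ampulla_elevation_deg))
}

#' Re-scale a human specification back into the bench-model regime
#'
#' Inverse of [unscale_model()].  The model fluid density is a free choice of
#' the bench design (it does not follow from the similarity rules), so it must
#' be supplied; with the original value the round trip is exact.
#'
#' @param materials A human-regime `material_spec`.
#' @param scaling A [scaling_spec()].
#' @param model_fluid_density Fluid density of the bench model (kg/m^3).
#' @return A `material_spec` with regime `"scaled_model"`.
#' @export
rescale_model <- function(materials, scaling = scaling_spec(),
                          model_fluid_density = 945) {
  stopifnot(inherits(materials, "material_spec"),
            inherits(scaling, "scaling_spec"))
  if (materials$regime != "human") {
    stop("invalid parameter `materials`: regime must be \"human\"",
         call. = FALSE)
  }
  f <- scaling$geometric_factor
  ratio_human <- materials$particle_density / materials$fluid_density
  material_spec(
    fluid_kinematic_viscosity = materials$fluid_kinematic_viscosity * f^2,
    fluid_density = model_fluid_density,
    particle_diameter = materials$particle_diameter * f,
    particle_density = model_fluid_density * (1 + f * (ratio_human - 1)),
    regime = "scaled_model")
}

#' Stokes settling velocity of the canalith
#'
#' Terminal velocity of a small sphere in viscous fluid,
#' `v_s = (rho_p - rho_e) * g * D^2 / (18 * rho_e * nu * lambda)`,
#' strictly proportional to the squared diameter.  `lambda >= 1` is a drag
#' correction for settling along the duct wall (lambda = 1 recovers free
#' Stokes drag); it is the model's single free parameter and is normally
#' obtained by [calibrate_drag()].
#'
#' @param materials A [material_spec()].
#' @param drag_correction Wall-drag correction lambda (>= 1).
#' @param gravity Gravitational acceleration (m/s^2).
#' @return Settling speed (m/s).
#' @examples
#' settling_velocity(model_materials())  # ~9.15e-3 m/s at lambda = 1
#' @export
settling_velocity <- function(materials, drag_correction = 1,
                              gravity = .canalith_gravity) {
  stopifnot(inherits(materials, "material_spec"))
  if (!is.numeric(drag_correction) || length(drag_correction) != 1L ||
      is.na(drag_correction) || drag_correction < 1) {
    stop("invalid parameter `drag_correction`: must be >= 1", call. = FALSE)
  }
  .check_positive(gravity, "gravity")
  with(materials,
       (particle_density - fluid_density) * gravity * particle_diameter^2 /
         (18 * fluid_density * fluid_kinematic_viscosity * drag_correction))
}

#' Settling slowdown of the bench model relative to the human canal
#'
#' Ratio of the times a particle needs to settle over geometrically
#' corresponding distances in the bench model and in the human canal:
#' `t_model / t_human = (f * L / v_model) / (L / v_human) = f * v_human /
#' v_model`, independent of the distance L.  A value of 1 means perfect
#' dynamic similarity; the realized bench pairing settles slightly more
#' slowly than the human reference, so its predicted critical times are
#' conservative.
#'
#' @param model Bench-model `material_spec`.
#' @param human Human-regime `material_spec`; diameters must be geometrically
#'   paired, `D_model = f * D_human`.
#' @param scaling A [scaling_spec()].
#' @param drag_correction,gravity Passed to [settling_velocity()] (identical
#'   for both regimes, so they cancel except through lambda's definition).
#' @return The dimensionless slowdown ratio `t_model / t_human`.
#' @examples
#' settling_slowdown(model_materials(), human_materials())  # ~1.27
#' @export
settling_slowdown <- function(model, human, scaling = scaling_spec(),
                              drag_correction = 1,
                              gravity = .canalith_gravity) {
  stopifnot(inherits(model, "material_spec"), inherits(human, "material_spec"))
  f <- scaling$geometric_factor
  if (abs(model$particle_diameter - f * human$particle_diameter) >
      1e-9 * model$particle_diameter) {
    stop("unpaired diameters: `model` diameter must equal ",
         "geometric_factor * `human` diameter", call. = FALSE)
  }
  v_m <- settling_velocity(model, drag_correction, gravity)
  v_h <- settling_velocity(human, drag_correction, gravity)
  f * v_h / v_m
}
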