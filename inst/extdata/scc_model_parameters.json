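{
  "canal": {
    "major_radius_mm": 16,
    "duct_radius_mm": 0.75,
    "duct_span_deg": 240,
    "upright_ampulla_elevation_deg": 32
  },
  "materials": {
    "fluid_kinematic_viscosity_m2_s": 2.7e-05,
    "fluid_density_kg_m3": 945,
    "particle_diameter_um": [180, 250],
    "particle_density_kg_m3": 7800,
    "regime": "scaled_model"
  },
  "scaling": {
    "geometric_factor": 5,
    "reference_endolymph_density_kg_m3": 1000,
    "reference_otoconia_density_kg_m3": 2700
  },
  "unscaled_reference": {
    "major_radius_mm": 3.2,
    "duct_radius_mm": 0.15,
    "fluid_viscosity_m2_s": 1.08e-06,
    "fluid_density_kg_m3": 1000,
    "particle_diameter_um": [36, 50],
    "particle_density_kg_m3": 2450
  }
}
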