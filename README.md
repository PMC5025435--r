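# canalith

Mechanistic simulation of canalith repositioning maneuvers in a
semicircular canal (SCC) model.

Benign paroxysmal positional vertigo is usually caused by canalolithiasis:
otoconial debris floating freely in a semicircular canal. The Sémont
liberatory maneuver treats it with two rapid body rotations separated by a
resting period. `canalith` is an in-silico twin of a scaled bench model of
this situation — a five-fold enlarged SCC duct with a single settling
microsphere, rotated by a stepper motor or a hand-operated lever arm — for
researchers and clinicians who want to explore *why* and *when* the
maneuver works: how the critical resting time depends on the extension
angle beyond the horizontal, the maneuver velocity, the particle size, and
the pivot location.

## The model

The canalith is a single sphere settling in the overdamped Stokes regime
along a circular duct of radius *R*; its arc position ψ (degrees from the
ampulla) obeys the overdamped-pendulum equation

    dψ/dt = −(v_s,eff / R) · sin(ψ − ψ_bottom,eff(t)),
    v_s   = (ρ_p − ρ_e) g D² / (18 ρ_e ν λ),

where ψ_bottom is the gravitationally lowest duct point for the current
canal orientation β(t) (effective gravity includes the centrifugal and
tangential inertial terms of a lever-arm pivot), and λ ≥ 1 is a wall-drag
correction — the model's single free parameter, calibrated against one
reference experiment. The duct ends absorb: the ampulla end means failure,
the utricle end success. On top of the transport core sit the
dynamic-similarity scaling laws between the bench model and the human
canal, a parametrized maneuver generator, a seeded synthetic noisy-operator
model, and the experimental protocol layer (critical-resting-time scans,
drag calibration, grid replication, clinical recommendations).

## Worked example

```r
library(canalith)

canal     <- canal_geometry()      # bench geometry: R = 16 mm, ampulla 32 deg down
materials <- model_materials()     # 250 um steel sphere in the viscous endolymph analogue

# Calibrate the wall drag on the 30-degree reference cell (9 s critical time)
lambda <- calibrate_drag(
  experiment_config(canal, materials, NA, 30, 90),
  target_critical_time_s = 9)
round(lambda, 2)
#> [1] 4.53

# Predict the critical resting time of the headline configuration:
# alpha+ = 20 deg, v = 90 deg/s, stepper kinematics
cfg <- experiment_config(canal, materials, lambda, 20, 90)
find_critical_time(cfg)
#> <critical_time_result> mode: deterministic
#>  critical resting time: 13 s (refined: 12.19 s)
#>  scanned 10 resting time(s)

# A single maneuver, start to finish
traj <- simulate_maneuver(canal, materials, lambda,
                          build_trace(maneuver_spec(20, 135, 45),
                                      sample_step = 0.01))
traj
#> <canalith_trajectory> in_utricle at t = 60.04858 s
#>  end of phase: move1=62.1, rest=167.48, move2=161.57, final=240 deg
```

The calibrated drag correction (4.53) says the sphere settles ~4.5 times
slower along the duct wall than free Stokes drag predicts. The headline
cell needs at least 13 s of rest (bench value: 16 s); the trajectory shows
the mechanism — the particle lags to 62.1° during the first movement,
settles to the low point at 168°, and the second movement leaves it at
161.6°, past the 128° apex, so it runs out into the utricle (ψ = 240°).

Scale the result to a patient-relevant otoconium:

```r
recommend_maneuver(25, reference_critical_time_s = 11)
#> <maneuver_recommendation> for 25 um otoconia
#>   resting time >= 45 s (raw 44 s, multiplier 4 )
#>   movements: 110 deg then 220 deg at ~ 135 deg/s
```

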