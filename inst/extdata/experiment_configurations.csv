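setup,particle_diameter_um,extension_angle_deg,maneuver_velocity_deg_s,reference_critical_time_s,reference_onset_time_s
stepper,180,20,90,29,NA
stepper,180,20,135,26,NA
stepper,180,20,180,24,NA
stepper,250,0,90,NA,NA
stepper,250,0,135,NA,NA
stepper,250,0,180,NA,NA
stepper,250,10,90,NA,NA
stepper,250,10,135,33,NA
stepper,250,10,180,26,NA
stepper,250,20,90,16,NA
stepper,250,20,135,13,NA
stepper,250,20,180,12,NA
stepper,250,30,90,9,NA
stepper,250,30,135,8,NA
stepper,250,30,180,8,NA
lever,250,20,90,16,12
lever,250,20,135,11,8
lever,250,20,180,10,8
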