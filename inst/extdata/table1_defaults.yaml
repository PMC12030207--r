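# Central fasted-state physiology and disposition values with optimized
# variability settings; loaded by load_config() on top of package defaults.
physiology:
  mrt_stomach_fluid_h: 0.12
  mrt_si_fluid_h: 3.4
  mrt_stomach_particles_h: 0.27
  mrt_si_particles_h: 3.4
  vss_L_kg: 0.091249
  vol_stomach_mL: 50.0
  vol_si_mL: 105.0
  vol_colon_mL: 13.0
variability_cv_pct:
  mrt_stomach_fluid: 150.0
  mrt_si_fluid: 150.0
  mrt_stomach_particles: 150.0
  mrt_si_particles: 150.0
  vss: 10.0
  vol_stomach: 30.0
  vol_si: 30.0
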