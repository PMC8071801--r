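# End-to-end demo: synthesize indentation curves for the reference membrane
# composition, detect breakthrough events, and refit the nucleation model.
# The fitted line tension lands within 5% of the generating 6.93e-3 nN.
stages:
  - simulate_curves
  - analyze_curves
  - fit_nucleation
seed: 1
simulate_curves:
  n_curves: 800
  line_tension_N: 6.93e-12
  spreading_pressure_Nm: 9.49e-3
  radius_nm: 20
  spring_Nm: 0.060
  velocity_ms: 1.0e-6
  attempt_hz: 3000
  temperature_K: 298
analyze_curves:
  condition: reference
fit_nucleation:
  line_tension_N: 6.93e-12     # only instrument fields are used by the fit
  spreading_pressure_Nm: 9.49e-3
  radius_nm: 20
  spring_Nm: 0.060
  velocity_ms: 1.0e-6
  attempt_hz: 3000
  temperature_K: 298
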