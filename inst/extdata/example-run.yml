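# Example run configuration for the naagif CLI.
# naagif simulate --config example-run.yml --out spectrum.csv
design:
  period_top: 164        # nm
  period_bottom: 284     # nm
  n_periods_top: 100
  n_periods_bottom: 100
  layers_per_period: 8
  f_host_avg: 0.9
  f_ampl: 0.025
  f_drug: 0.025
  barrier_thickness: 40  # nm
  surface_layer_thickness: 0
  medium_index: 1.33     # water
materials:
  host: {type: cauchy, A: 1.62, B: 12000}
  drug: {type: lorentz, eps_inf: 1.96, resonance_wavelength: 530,
         strength: 0.05, damping: 0.17}
bands:
  signal: [504, 564]     # nm, bracketing the top-stack stopband
  reference: [881, 941]  # nm, bracketing the bottom-stack stopband
grid: {min: 400, max: 1000, step: 1}
angle: 0                 # degrees
seed: 0
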