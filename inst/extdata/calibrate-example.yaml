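# Grid-search calibration of the multi-arm threshold for the uncontrolled
# design hypotheses, controlling the FWER at 10% under the global null.
# Reduced grid and replicate count keep this example quick; drop the grid
# lines to use the full default grid.
design:
  K: 3
  n_max: 60
  schedule: [15, 30, 45, 60]
  controlled: false
  phi_eff: 0.45
  phi_tox: 0.30
  prior: [0.15, 0.30, 0.15, 0.40]
calibration:
  family: multi_arm
  H0: [0.15, 0.30, 0.15, 0.40]
  H1: [0.18, 0.42, 0.02, 0.38]
  fwer_target: 0.10
  lambda_grid: [0.5, 0.6, 0.7, 0.8, 0.9]
  gamma_grid: [0.5, 0.75, 1.0]
  R_cal: 2000
  seed: 1
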