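# Replicated simulation of the three-arm uncontrolled design under its
# least favourable configuration (arm 1 promising, arms 2-3 inadmissible).
design:
  K: 3
  n_max: 60
  schedule: [15, 30, 45, 60]
  controlled: false
  phi_eff: 0.45
  phi_tox: 0.30
  prior: [0.15, 0.30, 0.15, 0.40]
threshold:
  family: multi_arm
  lambda: 0.63
  gamma: 1.0
scenario:
  label: lfc
  arms:
    - joint: [0.18, 0.42, 0.02, 0.38]
    - joint: [0.15, 0.30, 0.15, 0.40]
    - joint: [0.15, 0.30, 0.15, 0.40]
  truth: [admissible, inadmissible, inadmissible]
accrual:
  mode: planned
replicates: 1000
seed: 42
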