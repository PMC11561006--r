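# Example run configuration for a synthetic desk-scale study.
# rivermrf calibrate --config example_config.yml --out runs/cal
grid:
  n_rows: 12
  n_cols: 13
  cell_size_m: 5
river:
  synthetic:
    seed: 4
    width: 1
parcels:
  cells:
    - [3, 4]
    - [6, 7]
    - [7, 1]
  total_year_count: 1
  n_trips: 10
K: 0.113
chain:
  n_sweeps: 15000
  tail_sweeps: 300
  seed: 1
temperatures:
  candidates: [1.0e-4, 1.0e-5]
  ratio: 100
tol: 0.02
# used by `rivermrf map` once g is calibrated:
params:
  g: 0.01
  T1: 1.0e-5
  T2: 1.0e-7
realizations:
  k: 5
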