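# Example run configuration for inst/scripts/simulate.R
landscape_file: null        # path to an AGC text grid; null = synthetic
landscape_args:
  n_rows: 60
  n_cols: 60
  fragment_areas: [26, 9, 4, 1]
  seed: 7
scenario: control
h: 0.05
years: 40
replicates: 3
seed: 1
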