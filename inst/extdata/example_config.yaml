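# Example end-to-end run configuration (synthetic survey).
seed: 42
pool:
  n_native: 20
  n_invader: 4
  n_terrestrial: 2
  n_sister_pairs: 0
reference:
  fraction_with_barcode: 1.0
design:
  n_water_column_sites: 2
  n_tide_pool_sites: 2
  n_shore_samples: 2
  reads_per_sample: 500
  error_rate: 0.005
  n_community_species: 15
  tide_pool_species: 5
  tide_pool_multiplier: 3
thresholds:
  identity: 0.97
  min_overlap: 30
  min_insert: 270
  similarity: 0.97
  primer_mismatches: 2
  max_mismatch_frac: 0.1
  contamination: 0.01
read_len: 250
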