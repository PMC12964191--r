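{
  "out_dir": "runs/k2_n100",
  "genotypes": {
    "n_individuals": 9139,
    "n_positions": 290522,
    "block_size": 10,
    "haplotype_pool": 8,
    "maf_range": [0.05, 0.5],
    "bp_spacing": 5000
  },
  "scenario": {
    "k": 2,
    "n_causal": 100,
    "case_fraction": 0.198489987963672
  },
  "model": {
    "preset": "genome-wide"
  },
  "m": 10,
  "m_null": 10,
  "method": "ig",
  "n_steps": 50,
  "theta_percentile": "strict",
  "n_reps": 100,
  "master_seed": 1
}
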