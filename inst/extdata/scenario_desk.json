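{
  "out_dir": "runs/desk",
  "genotypes": {
    "n_individuals": 2000,
    "n_positions": 5000,
    "block_size": 10,
    "haplotype_pool": 8,
    "maf_range": [0.05, 0.5],
    "bp_spacing": 5000
  },
  "scenario": {
    "k": 1,
    "n_causal": 20,
    "case_fraction": 0.198489987963672
  },
  "model": {
    "epochs": 200,
    "batch_size": 256,
    "n_val_cases": 50,
    "n_val_controls": 50
  },
  "m": 5,
  "m_null": 3,
  "method": "ig",
  "n_steps": 50,
  "theta_percentile": "strict",
  "n_reps": 100,
  "master_seed": 1
}
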