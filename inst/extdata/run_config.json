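{
  "cohort": {
    "config": {
      "seed": 1
    }
  },
  "features": ["annual_wear", "age_at_surgery"],
  "h": 0.7,
  "k": 5,
  "n_permutations": 5,
  "h_grid": {"min": 0.3, "max": 2.1, "step": 0.3},
  "subgroups": ["all", "male", "female"],
  "out_dir": "osteoKDE_run",
  "master_seed": 1
}
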