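{
  "simulate": {
    "n_individuals": 600,
    "n_flank_snps": 178,
    "n_del_probes": 6,
    "del_freq": 0.382,
    "n_del_origins": 8
  },
  "impute": {
    "n_ref": 100,
    "Ne": 20000,
    "thresholds": [0.7, 0.9],
    "runs": 10
  },
  "assoc": {
    "model": "genotypic",
    "covariates": ["sex", "ethnicity", "rs334"]
  },
  "evaluate": {
    "methods": ["truth", "cutoffs", "hclust", "mrm", "cart"]
  }
}
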