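{
  "command": "frobnicate",
  "seed": 1,
  "config": {
    "task": {
      "n_subjects": 22,
      "n_trials": 160,
      "value_grid": [0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8],
      "deadline_s": 0.75,
      "weighting_ratio": 5
    },
    "generator": {
      "model": "lca",
      "params": {}
    },
    "fitting": {
      "ibs_repeats": 1,
      "K_max": 500,
      "maxit": 120,
      "restarts": 2,
      "n_quantiles": 10,
      "strata": "ov",
      "dt": 0.005,
      "deadline": 0.75
    },
    "comparison": {
      "n_sim": 20,
      "n_boot": 10000
    },
    "sample_dt": 0.001,
    "seed": {}
  },
  "package_version": "0.1.0"
}
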