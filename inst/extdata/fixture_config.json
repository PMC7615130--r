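{
  "seed": 42,
  "out_dir": "deprivmap-fixture-out",
  "simulate": {
    "n_neighbourhoods": 4,
    "eas_per_neighbourhood": 25,
    "v_sd": 0,
    "raster_resolution_m": 60
  },
  "model": {
    "prior_family": "normal",
    "prior_scale": 0.98,
    "random_effects": false,
    "n_iter": 300,
    "burn_in": 200,
    "n_chains": 2,
    "thin": 1
  },
  "cv": {
    "fractions": [0.05, 0.10],
    "n_iter": 150,
    "burn_in": 100,
    "n_chains": 2
  },
  "predict": { "threshold": 0.8, "policy": "marginalize" },
  "lisa": {
    "variables": ["flush_toilet", "pop_density"],
    "n_perm": 99,
    "alpha": 0.05
  }
}
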