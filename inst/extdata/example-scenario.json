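{
  "architecture": "tGDc",
  "c": 0.9,
  "suppression": false,
  "life_history": {"N": 1000},
  "releases": {"first_day": 50, "n_releases": 5, "interval": 7, "size": 100},
  "sim_mode": "stochastic",
  "replicates": 2,
  "horizon_days": 365,
  "seed": 1
}
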