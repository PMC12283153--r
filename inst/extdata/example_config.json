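{
  "scenario": {
    "type": "typeI",
    "T": 500,
    "J": 1,
    "snr_brain": 3,
    "snr_meas": 5,
    "n_realizations": 5,
    "seed": 1
  },
  "model": { "n_sources": 3, "order": 2 },
  "inference": { "n_particles": 64, "n_iter": 150 },
  "methods": ["joint", "mcmv", "lcmv"]
}
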