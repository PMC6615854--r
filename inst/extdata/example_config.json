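{
  "comment": "Apolar reference bundle, non-treadmilling, desk-scale duration",
  "polarity": "apolar",
  "n_filaments": 30,
  "bundle_length": 2000,
  "lattice_spacing": 35,
  "box": [4000, 1500, 1500],
  "actin_uM": 5,
  "alpha_ratio": 0.1,
  "motor_ratio": 0.0225,
  "treadmilling": false,
  "duration": 100,
  "snapshot_interval": 10,
  "dt_chem": 0.05,
  "seed": 1
}
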