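{
  "comment": "Reduced smoke grid; the full campaign uses alpha:A in {0.01,0.05,0.1,0.25,0.4,0.6,0.8} x M:A in {0.0225,0.045,0.09,0.18,0.225,0.675} with 8 replicates of 2000 s",
  "alpha_ratios": [0.1],
  "motor_ratios": [0.0225, 0.675],
  "replicates": 2,
  "base_seed": 5,
  "config": {
    "n_filaments": 6, "bundle_length": 500, "box": [2000, 800, 800],
    "duration": 2, "dt_chem": 0.1, "snapshot_interval": 1, "polarity": "apolar"
  }
}
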