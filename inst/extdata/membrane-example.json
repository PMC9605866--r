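{
  "box": [400, 400],
  "area_per_lipid": 64,
  "z0": 19,
  "jitter_sd": 1,
  "noise_sd": 0.8,
  "composition": {"PE": 0.54, "PC": 0.32, "SM": 0.08, "CHOL": 0.06},
  "field": {
    "leaflet": ["lower"],
    "amplitude": [6],
    "cx": [200],
    "cy": [200],
    "sigma": [15]
  },
  "protein_radius": 30,
  "shell_multipliers": {"CHOL": 2},
  "n_frames": 50,
  "seed": 1
}
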