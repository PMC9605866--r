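{
  "n_traces": 2000,
  "n": 2,
  "p": 0.8,
  "unit": 100,
  "noise_sd": 10,
  "mean_bleach": 50,
  "n_frames": 200,
  "baseline": 0,
  "seed": 1
}
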