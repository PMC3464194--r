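{
  "reps": 50,
  "distances": [0.1, 0.2, 0.3],
  "conditions": {"vigor": [100, 50, 200], "gamma": [2, 2, 2]},
  "sigma_sdn_m": 1,
  "sigma_sin_s": 0.001
}
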