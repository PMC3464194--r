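{
  "n": 100,
  "grid": [0.35, 0.70, 1.05, 1.40, 1.75, 2.10, 2.45],
  "beta": 1,
  "unidentifiable": "boundary"
}
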