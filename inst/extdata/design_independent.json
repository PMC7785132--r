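{
  "K": 2,
  "prevalences": [0.2, 0.8],
  "b": 0,
  "rule": "independent",
  "alpha": 0.05,
  "weights": [0.75, 0.25],
  "weights_are_squared": true,
  "tilde_offset_days": 1279,
  "dropped_followed_to_tilde": false
}
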