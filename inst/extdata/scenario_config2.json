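{
  "theta": [-0.2231, -0.0953, 0.3364, 0.4055],
  "gamma": 0.5,
  "lambda_c": 0.034657359027997264,
  "prevalences": [0.25, 0.25, 0.25, 0.25],
  "n_patients": 2200,
  "accrual_days": 730,
  "allocation": 0.5,
  "interim_events": 300,
  "stage2_events": 300,
  "tilde_offset_days": 250,
  "rule": "adaptive_threshold",
  "b": 0,
  "alpha": 0.05
}
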