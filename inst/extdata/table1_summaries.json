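{
  "partitions": [
    {
      "theta1": -0.902, "sigma2_1": 0.191,
      "thetaN": -0.746, "sigma2_N": 0.089,
      "theta2": -0.609, "sigma2_2": 0.167
    },
    {
      "theta1": -0.419, "sigma2_1": 0.103,
      "thetaN": -0.362, "sigma2_N": 0.053,
      "theta2": -0.301, "sigma2_2": 0.108
    }
  ]
}
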