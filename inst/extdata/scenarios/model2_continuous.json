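{
  "model_id": 2,
  "label": "Model 2, continuous 25 uM exposure (MCF7)",
  "za": {"kZY": 0.007, "kXY": 0.004, "kYZ": 0.001, "rhoZY": 25.46,
         "kXZ": 0, "Ystar_plus": 0},
  "ag": {"kXG": 0.081, "kXGU": 0.051, "lambdaUBG": 1.806,
         "kBUZ": 0.099, "kUBG": 0.168, "G0": 27.32, "U0": 100},
  "design": {"mode": "continuous", "Y0": 25,
             "sample_times": [1, 3, 6, 12, 18, 24, 48]}
}
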