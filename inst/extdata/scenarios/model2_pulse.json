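{
  "model_id": 2,
  "label": "Model 2, 1 h pulse exposure then medium replacement",
  "za": {"kZY": 0.607, "kXY": 0.029, "kYZ": 18.06, "rhoZY": 14.91,
         "kXZ": 0, "Ystar_plus": 0},
  "ag": {"kXG": 0, "kXGU": 0.224, "lambdaUBG": 0.017,
         "kBUZ": 0.150, "kUBG": 0.057, "G0": 0.988, "U0": 100},
  "design": {"mode": "pulse", "Y0": 25, "t_star": 1,
             "sample_times": [0, 1, 3, 6, 12, 18, 24, 48]}
}
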