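{
  "model_id": 1,
  "label": "Model 1, 1 h pulse exposure then medium replacement",
  "za": {"kZY": 0.607, "kXY": 0.029, "kYZ": 18.06, "rhoZY": 14.91,
         "kXZ": 0, "Ystar_plus": 0},
  "ag": {"kXG": 0, "kXGZ": 2.391, "lambdaGZ": 0.377, "G0": 2.704},
  "design": {"mode": "pulse", "Y0": 25, "t_star": 1,
             "sample_times": [0, 1, 3, 6, 12, 18, 24, 48]}
}
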