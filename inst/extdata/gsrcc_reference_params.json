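[
  {"t_stage": "T1", "alpha": 0.06938207, "beta": 1.8877199,
   "alpha_ci": [0.03686795, 0.1235056], "beta_ci": [1.2074176, 4.266865]},
  {"t_stage": "T2", "alpha": 0.42578161, "beta": 2.2180490,
   "alpha_ci": [0.26941777, 0.7476104], "beta_ci": [1.4385130, 4.397587]},
  {"t_stage": "T3", "alpha": 0.48686973, "beta": 1.2430379,
   "alpha_ci": [0.38153144, 0.6422990], "beta_ci": [0.9737503, 1.666755]},
  {"t_stage": "T4", "alpha": 0.80543434, "beta": 0.8710085,
   "alpha_ci": [0.64691993, 1.0226410], "beta_ci": [0.7142595, 1.084519]}
]
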