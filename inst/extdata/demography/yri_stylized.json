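{
  "name": "yri_stylized",
  "comment": "Stylized piecewise-constant Yoruba size history spanning 55,000 generations (no out-of-Africa bottleneck). Documented stand-in for an archived MSMC-inferred trajectory.",
  "N_ancestral": 20000,
  "burn_in_multiplier": 10,
  "epochs": [
    {"t_start": 55000, "t_end": 500, "N_start": 20000, "growth_rate": 0},
    {"t_start": 500, "t_end": 50, "N_start": 25000, "growth_rate": 0},
    {"t_start": 50, "t_end": 0, "N_start": 25000, "growth_rate": 0}
  ]
}
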