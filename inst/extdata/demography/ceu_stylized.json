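{
  "name": "ceu_stylized",
  "comment": "Stylized piecewise-constant European size history spanning 55,000 generations: ancestral 14,448, out-of-Africa bottleneck, recovery, and a pre-expansion size of 17,914 chosen so that 4.5% exponential growth over the final 196 generations reaches ~1e8 at present. This is a documented stand-in for an archived MSMC-inferred trajectory; supply your own epoch table to reproduce one.",
  "N_ancestral": 14448,
  "burn_in_multiplier": 10,
  "epochs": [
    {"t_start": 55000, "t_end": 3500, "N_start": 14448, "growth_rate": 0},
    {"t_start": 3500, "t_end": 1500, "N_start": 3000, "growth_rate": 0},
    {"t_start": 1500, "t_end": 500, "N_start": 10000, "growth_rate": 0},
    {"t_start": 500, "t_end": 50, "N_start": 17914, "growth_rate": 0},
    {"t_start": 50, "t_end": 0, "N_start": 17914, "growth_rate": 0}
  ]
}
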