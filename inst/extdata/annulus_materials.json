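[
  {
    "region": "anterior",
    "C10_MPa": 0.061,
    "D_per_MPa": 0.311,
    "k1_MPa": 24,
    "k2": 1700,
    "kappa": 0.01,
    "theta_deg": 29
  },
  {
    "region": "lateral",
    "C10_MPa": 0.033,
    "D_per_MPa": 0.615,
    "k1_MPa": 5,
    "k2": 940,
    "kappa": 0.01,
    "theta_deg": 30
  },
  {
    "region": "posterior",
    "C10_MPa": 0.077,
    "D_per_MPa": 0.261,
    "k1_MPa": 1,
    "k2": 50,
    "kappa": 0.01,
    "theta_deg": 28
  }
]
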