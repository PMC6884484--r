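{
  "tissues": {
    "thalamus":    {"beta1": 3.13, "beta2": 1.25,  "beta3": 0.67, "span": 0.6, "offset": 0.15},
    "hippocampus": {"beta1": 3.13, "beta2": 1.67,  "beta3": 2.5,  "span": 0.5, "offset": 0},
    "caudate":     {"beta1": 3.13, "beta2": 0.625, "beta3": 0.83, "span": 0.5, "offset": 0},
    "putamen":     {"beta1": 3.13, "beta2": 0.72,  "beta3": 1,    "span": 0.5, "offset": 0.1},
    "pallidum":    {"beta1": 3.13, "beta2": 0.83,  "beta3": 1.25, "span": 0.5, "offset": 0.15},
    "amygdala":    {"beta1": 3.13, "beta2": 1,     "beta3": 0.25, "span": 0.5, "offset": -0.05}
  }
}
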