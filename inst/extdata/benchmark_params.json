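{
  "comment": "Per-model parameter sampling ranges for the simulation benchmark. Ranges are chosen so that adjacent model families are distinguishable at n=500 samples: Poisson rates well above 1, negative binomial strongly overdispersed, zero-inflation mass 0.2-0.6, Gaussian mixture components separated by at least 3 component standard deviations, Beta-Poisson shapes below 1 so the mixing density is U-shaped (bursting), and left-truncation floors censoring a 15-40% minority of the mass.",
  "P":    {"lambda": [2, 20]},
  "NB":   {"size": [1, 4], "mu": [5, 40]},
  "G":    {"mu": [2, 8], "sigma": [0.5, 2]},
  "ZIP":  {"lambda": [5, 20], "pi0": [0.2, 0.6]},
  "ZINB": {"size": [2, 5], "mu": [10, 40], "pi0": [0.2, 0.6]},
  "ZIG":  {"mu": [3, 8], "sigma": [0.4, 1], "pi0": [0.2, 0.6]},
  "LTG":  {"mu": [3, 8], "sigma": [0.5, 1.5], "zcut_offset": [0.5, 1.3]},
  "BP":   {"alpha": [0.2, 0.5], "beta": [0.2, 0.5], "scale": [40, 100]},
  "MG":   {"k": [2, 3], "mu1": [1, 2], "gap": [2.5, 4], "sigma": [0.4, 0.8],
           "min_weight": 0.15},
  "ZIMG": {"k": [2, 3], "mu1": [2.5, 3.5], "gap": [2.5, 4],
           "sigma": [0.4, 0.8], "min_weight": 0.15, "pi0": [0.2, 0.5]},
  "LTMG": {"k": [2, 3], "mu1": [0, 0.6], "sigma1": [0.7, 1],
           "w1": [0.25, 0.45], "mu2": [3.5, 4.5], "gap": [2.5, 4],
           "sigma": [0.4, 0.8], "zcut": 1}
}
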