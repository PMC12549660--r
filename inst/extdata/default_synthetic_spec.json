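{
  "cohorts": ["A", "B"],
  "sizes": {
    "A": 190,
    "B": 260
  },
  "prevalence": {
    "A": 0.51,
    "B": 0.7
  },
  "rho_target": {
    "A": 0.52,
    "B": 0.47
  },
  "rho_within": {
    "A": 0.035,
    "B": 0.19
  },
  "fraction_missing_csf_ratio": 0.0666666666666667,
  "rng_seed": 20260101,
  "groups": {
    "A": {
      "positive": {
        "age": [72.5, 68.3, 76],
        "mmse": [27, 25, 29],
        "storage_years": [0.8, 0.33, 1.3],
        "plasma_ab40": [233.9, 206.4, 264.2],
        "plasma_ratio": [0.185, 0.174, 0.204],
        "csf_ab40": [13384, 10552.3, 16648.8],
        "csf_ratio": [0.049, 0.042, 0.058],
        "csf_ptau181": [96.2, 73.4, 143.2],
        "apoe_e4_probs": [0.447552447552447, 0.437562437562438, 0.114885114885115],
        "female_frac": 0.594
      },
      "negative": {
        "age": [66.5, 61, 72],
        "mmse": [28, 26, 30],
        "storage_years": [0.6, 0.4, 1.3],
        "plasma_ab40": [216.7, 201.2, 252.2],
        "plasma_ratio": [0.216, 0.198, 0.227],
        "csf_ab40": [12405, 9258.5, 15813.3],
        "csf_ratio": [0.109, 0.099, 0.114],
        "csf_ptau181": [38.8, 29.5, 50.3],
        "apoe_e4_probs": [0.809, 0.191, 0],
        "female_frac": 0.521
      }
    },
    "B": {
      "positive": {
        "age": [74, 71, 77],
        "mmse": [26, 24, 27.8],
        "storage_years": [1.5, 0.9, 2.2],
        "plasma_ab40": [226.3, 199.9, 255.9],
        "plasma_ratio": [0.195, 0.18, 0.212],
        "csf_ab40": [10726, 8147, 13469],
        "csf_ratio": [0.043, 0.035, 0.049],
        "csf_ptau181": [94, 69.1, 127.5],
        "apoe_e4_probs": [0.429, 0.5, 0.071],
        "female_frac": 0.637
      },
      "negative": {
        "age": [70, 65, 74.3],
        "mmse": [27, 24.3, 28],
        "storage_years": [1.5, 0.8, 2.3],
        "plasma_ab40": [226, 206.1, 265.1],
        "plasma_ratio": [0.221, 0.209, 0.24],
        "csf_ab40": [10799, 8047.3, 12982],
        "csf_ratio": [0.089, 0.081, 0.102],
        "csf_ptau181": [39.5, 29.7, 48.3],
        "apoe_e4_probs": [0.859, 0.115, 0.026],
        "female_frac": 0.551
      }
    }
  },
  "rules": {
    "A": {
      "ratio_cutoff": 0.068,
      "fallback_cutoff": 0.0815
    },
    "B": {
      "ratio_cutoff": 0.069,
      "fallback_cutoff": 0.0815
    }
  }
}
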