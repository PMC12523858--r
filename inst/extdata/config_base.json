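{
  "settings": {
    "horizon_years": 40,
    "cycle_days": 21,
    "discount_rate": 0.03,
    "wtp": 101949,
    "conversion_factor": 0.9198,
    "reference_conversion_factor": 0.9198,
    "sugemalimab_price_per_600mg": 1720,
    "price_multiplier": 1,
    "duration_rule": "median_duration"
  },
  "population": "cps5",
  "survival_block": "base",
  "costs": {
    "admin": 1226,
    "pf_nonmed": 25925,
    "supportive": 63077,
    "pd_drug": 4682,
    "pd_admin": 2018,
    "terminal": 54893,
    "ae_neutropenia": 769,
    "ae_anemia": 1494
  },
  "disutilities": {
    "neutropenia": 0.2,
    "anemia": 0.07
  },
  "strategies": {
    "intervention": {
      "name": "sugemalimab + CAPOX",
      "os": {
        "family": "loglogistic",
        "params": [1.904, 16.86]
      },
      "pfs": {
        "family": "loglogistic",
        "params": [2.212, 9.015]
      },
      "utilities": {
        "pf": 0.812,
        "pd": 0.746
      },
      "ae_probs": {
        "neutropenia": 0.141,
        "anemia": 0.183
      },
      "drugs": {
        "sugemalimab": {
          "annual_cost": 59814,
          "rule_based": true
        },
        "capox": {
          "annual_cost": 8959,
          "cap_months": 4.13963039014374
        }
      },
      "duration_caps": {
        "median_duration": 6.3,
        "median_pfs": 7.72,
        "protocol_max": 24,
        "until_progression": "Inf"
      }
    },
    "comparator": {
      "name": "CAPOX",
      "os": {
        "family": "loglogistic",
        "params": [2.004, 13.331]
      },
      "pfs": {
        "family": "loglogistic",
        "params": [2.445, 7.305]
      },
      "utilities": {
        "pf": 0.798,
        "pd": 0.721
      },
      "ae_probs": {
        "neutropenia": 0.143,
        "anemia": 0.16
      },
      "drugs": {
        "capox": {
          "annual_cost": 8959,
          "cap_months": 4.13963039014374
        }
      },
      "duration_caps": {
        "median_duration": 5.2,
        "median_pfs": 6.24,
        "protocol_max": 4.13963039014374,
        "until_progression": "Inf"
      }
    }
  }
}
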