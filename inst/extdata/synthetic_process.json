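{
  "cqas": [
    {
      "name": "hcp",
      "direction": "impurity",
      "unit": "ng/mg",
      "ds_spec": 10,
      "fit_scale": "log"
    },
    {
      "name": "aggregates",
      "direction": "impurity",
      "unit": "%",
      "ds_spec": 2
    },
    {
      "name": "monomer",
      "direction": "purity",
      "unit": "%",
      "ds_spec": 98
    }
  ],
  "uos": [
    {
      "id": 1,
      "name": "Harvest",
      "pps": [
        {
          "name": "temperature",
          "set_point": 20,
          "design_range": [16, 24]
        }
      ],
      "models": {
        "hcp": {
          "type": "manufacturing_sc"
        }
      }
    },
    {
      "id": 2,
      "name": "Capture",
      "pps": [
        {
          "name": "load_pH",
          "set_point": 7.2,
          "design_range": [6.8, 7.6]
        },
        {
          "name": "load_cond",
          "set_point": 5,
          "design_range": [4, 6]
        }
      ],
      "models": {
        "hcp": {
          "type": "combined",
          "factors": [
            "load_pH"
          ],
          "design": "ofat"
        },
        "aggregates": {
          "type": "manufacturing_sc"
        },
        "monomer": {
          "type": "manufacturing_sc"
        }
      }
    },
    {
      "id": 3,
      "name": "VI",
      "pps": [
        {
          "name": "stirrer_speed",
          "set_point": 200,
          "design_range": [150, 250]
        }
      ],
      "models": {
        "hcp": {
          "type": "manufacturing_sc"
        },
        "aggregates": {
          "type": "manufacturing_sc"
        },
        "monomer": {
          "type": "manufacturing_sc"
        }
      }
    },
    {
      "id": 4,
      "name": "DF",
      "models": {
        "hcp": {
          "type": "sc"
        },
        "aggregates": {
          "type": "sc"
        },
        "monomer": {
          "type": "sc"
        }
      }
    },
    {
      "id": 5,
      "name": "AEX",
      "pps": [
        {
          "name": "eq_pH",
          "set_point": 7.5,
          "design_range": [7, 8]
        }
      ],
      "models": {
        "hcp": {
          "type": "sc"
        },
        "aggregates": {
          "type": "sc"
        },
        "monomer": {
          "type": "sc"
        }
      }
    },
    {
      "id": 6,
      "name": "CEX",
      "pps": [
        {
          "name": "elu_cond",
          "set_point": 12,
          "design_range": [10, 14]
        },
        {
          "name": "elu_pH",
          "set_point": 5.5,
          "design_range": [5, 6]
        }
      ],
      "models": {
        "hcp": {
          "type": "doe",
          "factors": [
            "elu_cond",
            "elu_pH"
          ],
          "design": "grid5x3"
        },
        "aggregates": {
          "type": "doe",
          "factors": [
            "elu_cond",
            "elu_pH"
          ],
          "design": "grid5x3"
        },
        "monomer": {
          "type": "combined",
          "factors": [
            "elu_pH"
          ],
          "design": "grid5x3"
        }
      }
    },
    {
      "id": 7,
      "name": "VF",
      "models": {
        "hcp": {
          "type": "ds_spec_fallback"
        },
        "aggregates": {
          "type": "manufacturing_sc"
        },
        "monomer": {
          "type": "manufacturing_sc"
        }
      }
    },
    {
      "id": 8,
      "name": "HIC",
      "pps": [
        {
          "name": "hic_pH",
          "set_point": 6.8,
          "design_range": [6.4, 7.2]
        },
        {
          "name": "hic_cond",
          "set_point": 8,
          "design_range": [6, 10]
        },
        {
          "name": "hic_temp",
          "set_point": 22,
          "design_range": [18, 26]
        }
      ],
      "models": {
        "aggregates": {
          "type": "doe",
          "factors": [
            "hic_pH",
            "hic_cond",
            "hic_temp"
          ],
          "design": "ccf"
        },
        "monomer": {
          "type": "doe",
          "factors": [
            "hic_pH",
            "hic_cond",
            "hic_temp"
          ],
          "design": "ccf"
        }
      }
    },
    {
      "id": 9,
      "name": "UFDF",
      "models": {
        "aggregates": {
          "type": "manufacturing_sc"
        },
        "monomer": {
          "type": "sc"
        }
      }
    }
  ],
  "ranges": {
    "hcp": [1, 6],
    "aggregates": [2, 9],
    "monomer": [2, 9]
  },
  "simulation": {
    "n_runs": 400,
    "seed": 1
  }
}
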