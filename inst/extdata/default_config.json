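{
  "scoring_tables": {
    "bmi": {
      "unit": "kg/m2",
      "direction": "lower",
      "male": {
        "breaks": [23.9, 25.5, 27.9, 30, 35],
        "scores": [100, 80, 60, 40, 0]
      },
      "female": {
        "breaks": [23.9, 25.5, 27.9, 30, 35],
        "scores": [100, 80, 60, 40, 0]
      }
    },
    "vital_capacity": {
      "unit": "mL",
      "direction": "higher",
      "male": {
        "breaks": [2000, 2600, 3100, 4300, 5040],
        "scores": [0, 40, 60, 80, 100]
      },
      "female": {
        "breaks": [1200, 1600, 2000, 3000, 3400],
        "scores": [0, 40, 60, 80, 100]
      }
    },
    "sit_and_reach": {
      "unit": "cm",
      "direction": "higher",
      "male": {
        "breaks": [-10, -2, 4, 11.5, 25],
        "scores": [0, 40, 60, 80, 100]
      },
      "female": {
        "breaks": [-5, 2, 6, 14, 25.8],
        "scores": [0, 40, 60, 80, 100]
      }
    },
    "long_jump": {
      "unit": "cm",
      "direction": "higher",
      "male": {
        "breaks": [160, 185, 208, 240, 273],
        "scores": [0, 40, 60, 80, 100]
      },
      "female": {
        "breaks": [110, 130, 151, 181, 207],
        "scores": [0, 40, 60, 80, 100]
      }
    },
    "sprint_50m": {
      "unit": "s",
      "direction": "lower",
      "male": {
        "breaks": [6.7, 7.1, 8.4, 9.8, 11],
        "scores": [100, 80, 60, 40, 0]
      },
      "female": {
        "breaks": [7.5, 8.3, 10, 11.2, 12.5],
        "scores": [100, 80, 60, 40, 0]
      }
    },
    "endurance_run": {
      "unit": "s",
      "direction": "lower",
      "male": {
        "breaks": [197, 222, 272, 305, 360],
        "scores": [100, 80, 60, 40, 0]
      },
      "female": {
        "breaks": [198, 222, 274, 300, 340],
        "scores": [100, 80, 60, 40, 0]
      }
    },
    "strength_count": {
      "unit": "repetitions",
      "direction": "higher",
      "male": {
        "breaks": [0, 5, 10, 15, 19],
        "scores": [0, 40, 60, 80, 100]
      },
      "female": {
        "breaks": [10, 18, 26, 46, 56],
        "scores": [0, 40, 60, 80, 100]
      }
    }
  },
  "cuts": [60, 75, 85],
  "hierarchy": {
    "primaries": {
      "body_composition": {
        "children": "bmi"
      },
      "cardiorespiratory": {
        "children": ["vital_capacity", "endurance_run"],
        "matrix": [
          [1, 0.5],
          [2, 1]
        ]
      },
      "flexibility": {
        "children": "sit_and_reach"
      },
      "speed": {
        "children": "sprint_50m"
      },
      "strength": {
        "children": ["long_jump", "strength_count"],
        "matrix": [
          [1, 1],
          [1, 1]
        ]
      }
    },
    "primary_matrix": [
      [1, 0.333333333333333, 1, 0.5, 0.5],
      [3, 1, 3, 2, 2],
      [1, 0.333333333333333, 1, 0.5, 0.5],
      [2, 0.5, 2, 1, 1],
      [2, 0.5, 2, 1, 1]
    ]
  },
  "rules": [
    {
      "name": "endurance_deficit",
      "weakest": "cardiorespiratory",
      "at_most": "medium",
      "modes": ["aerobic running program", "swimming", "cycling"],
      "rationale": "low cardiorespiratory grade: build aerobic base"
    },
    {
      "name": "strength_deficit",
      "weakest": "strength",
      "at_most": "medium",
      "modes": ["resistance circuit", "bodyweight strength training"],
      "rationale": "low strength grade: progressive resistance work"
    },
    {
      "name": "flexibility_deficit",
      "weakest": "flexibility",
      "at_most": "medium",
      "modes": ["stretching routine", "yoga"],
      "rationale": "low flexibility grade: mobility work"
    },
    {
      "name": "speed_deficit",
      "weakest": "speed",
      "at_most": "medium",
      "modes": ["sprint intervals", "agility drills"],
      "rationale": "low speed grade: anaerobic/neuromuscular training"
    },
    {
      "name": "body_composition_deficit",
      "weakest": "body_composition",
      "at_most": "medium",
      "modes": ["mixed aerobic training", "dietary guidance"],
      "rationale": "unfavourable body composition: volume + diet"
    },
    {
      "name": "maintenance",
      "modes": ["maintenance mixed training", "recreational sports"],
      "rationale": "no weak dimension: keep a balanced routine"
    }
  ],
  "options": {
    "method": "binary",
    "max_depth": 25,
    "positive": null
  }
}
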