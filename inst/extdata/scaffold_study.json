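{
  "name": "load_bearing_bte_composite_study",
  "note": "Five biodegradable polymer-matrix composite scaffold candidates for load-bearing bone tissue engineering, scored on six criteria. Property TFNs (C1-C5) are literature-derived inter-study ranges. The C6 manufacturing-cost-index TFNs are a PACKAGE DEFAULT ASSUMPTION: linguistic cost ratings (A1 L, A2 L, A3 M, A4 H, A5 M) mapped through the 1-9 linguistic scale, not source data; override the matrix to change them. The published_ranking block holds the reference study's printed ranking table, shipped as comparison data.",
  "alternatives": [
    {"code": "A1", "name": "PLA/HA",  "material": "PLA/Hydroxyapatite",   "label": "Optimal"},
    {"code": "A2", "name": "PCL/HA",  "material": "PCL/Hydroxyapatite",   "label": "Sub-optimal—Low Strength"},
    {"code": "A3", "name": "PLGA/BG", "material": "PLGA/Bioactive Glass", "label": "Sub-optimal—Rapid Degradation"},
    {"code": "A4", "name": "PLA/CNT", "material": "PLA/Carbon Nanotubes", "label": "Suitable—High Strength"},
    {"code": "A5", "name": "PLA/Mg",  "material": "PLA/Magnesium",        "label": "Suitable—Balanced"}
  ],
  "criteria": [
    {"id": "C1", "name": "Compressive Strength", "units": "MPa",   "direction": "benefit"},
    {"id": "C2", "name": "Elastic Modulus",      "units": "GPa",   "direction": "benefit"},
    {"id": "C3", "name": "Porosity",             "units": "%",     "direction": "benefit"},
    {"id": "C4", "name": "Degradation Rate",     "units": "weeks", "direction": "target_range", "target": [12, 26]},
    {"id": "C5", "name": "Cell Viability",       "units": "%",     "direction": "benefit"},
    {"id": "C6", "name": "Manufacturing Cost Index", "units": "1-9", "direction": "cost",
     "note": "package default assumption, see top-level note"}
  ],
  "matrix": {
    "A1": {"C1": [20, 45, 65],   "C2": [1.5, 3.5, 6.0], "C3": [40, 60, 70], "C4": [24, 48, 100], "C5": [85, 92, 99], "C6": [1, 3, 5]},
    "A2": {"C1": [3.5, 7.0, 11], "C2": [0.1, 0.2, 0.4], "C3": [60, 75, 90], "C4": [50, 100, 200], "C5": [90, 95, 99], "C6": [1, 3, 5]},
    "A3": {"C1": [2.0, 5.0, 15], "C2": [0.5, 1.0, 3.0], "C3": [80, 90, 95], "C4": [4, 8, 12],    "C5": [90, 96, 99], "C6": [3, 5, 7]},
    "A4": {"C1": [35, 47, 60],   "C2": [1.2, 1.7, 2.5], "C3": [20, 40, 50], "C4": [24, 48, 72],  "C5": [75, 85, 90], "C6": [5, 7, 9]},
    "A5": {"C1": [15, 30, 52],   "C2": [0.8, 1.5, 2.2], "C3": [30, 55, 70], "C4": [12, 16, 24],  "C5": [85, 90, 95], "C6": [3, 5, 7]}
  },
  "weights": [
    {"id": "C1", "local": [0.20, 0.25, 0.30], "global_pct": 25.2},
    {"id": "C2", "local": [0.15, 0.20, 0.25], "global_pct": 18.4},
    {"id": "C3", "local": [0.10, 0.15, 0.20], "global_pct": 12.1},
    {"id": "C4", "local": [0.10, 0.15, 0.20], "global_pct": 12.1},
    {"id": "C5", "local": [0.15, 0.20, 0.25], "global_pct": 21.5},
    {"id": "C6", "local": [0.05, 0.05, 0.10], "global_pct": 10.7}
  ],
  "published_ranking": [
    {"rank": 1, "code": "A1", "name": "PLA/Hydroxyapatite",   "cc": 0.677, "d_pos": 3.82, "d_neg": 8.01, "label": "Optimal"},
    {"rank": 2, "code": "A4", "name": "PLA/Carbon Nanotubes", "cc": 0.544, "d_pos": 5.14, "d_neg": 6.10, "label": "Suitable—High Strength"},
    {"rank": 3, "code": "A5", "name": "PLA/Magnesium",        "cc": 0.510, "d_pos": 5.49, "d_neg": 5.72, "label": "Suitable—Balanced"},
    {"rank": 4, "code": "A2", "name": "PCL/Hydroxyapatite",   "cc": 0.479, "d_pos": 5.81, "d_neg": 5.33, "label": "Sub-optimal—Low Strength"},
    {"rank": 5, "code": "A3", "name": "PLGA/Bioactive Glass", "cc": 0.452, "d_pos": 6.23, "d_neg": 5.12, "label": "Sub-optimal—Rapid Degradation"}
  ]
}
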