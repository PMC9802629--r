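{
  "comment": "Score tables for SOFA (six organ subscores, 0-4 each) and MEWS, encoded from the original score publications (Vincent 1996; Subbe 2001). Bands are half-open [lo, hi). Cardiovascular SOFA supports dose tiers but defaults to a binary vasopressor flag scored at the lowest pressor tier.",
  "sofa": {
    "respiratory": {
      "variable": "pao2_fio2",
      "bands": [
        {"lo": 0, "hi": 100, "score": 4},
        {"lo": 100, "hi": 200, "score": 3},
        {"lo": 200, "hi": 300, "score": 2},
        {"lo": 300, "hi": 400, "score": 1},
        {"lo": 400, "hi": null, "score": 0}
      ]
    },
    "coagulation": {
      "variable": "platelets",
      "bands": [
        {"lo": 0, "hi": 20, "score": 4},
        {"lo": 20, "hi": 50, "score": 3},
        {"lo": 50, "hi": 100, "score": 2},
        {"lo": 100, "hi": 150, "score": 1},
        {"lo": 150, "hi": null, "score": 0}
      ]
    },
    "liver": {
      "variable": "bilirubin",
      "bands": [
        {"lo": 0, "hi": 1.2, "score": 0},
        {"lo": 1.2, "hi": 2, "score": 1},
        {"lo": 2, "hi": 6, "score": 2},
        {"lo": 6, "hi": 12, "score": 3},
        {"lo": 12, "hi": null, "score": 4}
      ]
    },
    "cardiovascular": {
      "variable": "map_mmHg",
      "bands": [
        {"lo": 0, "hi": 70, "score": 1},
        {"lo": 70, "hi": null, "score": 0}
      ],
      "pressor_flag_score": 2,
      "pressor_tiers": [
        {"tier": "low", "score": 2},
        {"tier": "medium", "score": 3},
        {"tier": "high", "score": 4}
      ]
    },
    "neurologic": {
      "variable": "gcs",
      "bands": [
        {"lo": 3, "hi": 6, "score": 4},
        {"lo": 6, "hi": 10, "score": 3},
        {"lo": 10, "hi": 13, "score": 2},
        {"lo": 13, "hi": 15, "score": 1},
        {"lo": 15, "hi": null, "score": 0}
      ]
    },
    "renal": {
      "variable": "creatinine",
      "bands": [
        {"lo": 0, "hi": 1.2, "score": 0},
        {"lo": 1.2, "hi": 2, "score": 1},
        {"lo": 2, "hi": 3.5, "score": 2},
        {"lo": 3.5, "hi": 5, "score": 3},
        {"lo": 5, "hi": null, "score": 4}
      ]
    }
  },
  "mews": {
    "sbp": {
      "bands": [
        {"lo": 0, "hi": 71, "score": 3},
        {"lo": 71, "hi": 81, "score": 2},
        {"lo": 81, "hi": 101, "score": 1},
        {"lo": 101, "hi": 200, "score": 0},
        {"lo": 200, "hi": null, "score": 2}
      ]
    },
    "hr": {
      "bands": [
        {"lo": 0, "hi": 41, "score": 2},
        {"lo": 41, "hi": 51, "score": 1},
        {"lo": 51, "hi": 101, "score": 0},
        {"lo": 101, "hi": 111, "score": 1},
        {"lo": 111, "hi": 130, "score": 2},
        {"lo": 130, "hi": null, "score": 3}
      ]
    },
    "rr": {
      "bands": [
        {"lo": 0, "hi": 9, "score": 2},
        {"lo": 9, "hi": 15, "score": 0},
        {"lo": 15, "hi": 21, "score": 1},
        {"lo": 21, "hi": 30, "score": 2},
        {"lo": 30, "hi": null, "score": 3}
      ]
    },
    "temp_c": {
      "bands": [
        {"lo": 0, "hi": 35, "score": 2},
        {"lo": 35, "hi": 38.5, "score": 0},
        {"lo": 38.5, "hi": null, "score": 2}
      ]
    },
    "avpu": {
      "levels": {"Alert": 0, "Voice": 1, "Pain": 2, "Unresponsive": 3}
    }
  }
}
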