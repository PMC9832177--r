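[
  {
    "scale_name": "gad",
    "item_names": ["gad_1", "gad_2", "gad_3", "gad_4", "gad_5", "gad_6", "gad_7", "gad_8"],
    "response_min": [0, 0, 0, 0, 0, 0, 0, 0],
    "response_max": [2, 2, 2, 2, 2, 2, 2, 2],
    "scoring_rule": "sum"
  },
  {
    "scale_name": "subuse",
    "item_names": ["alcohol", "marijuana", "tobacco"],
    "response_min": [0, 0, 0],
    "response_max": [7, 7, 7],
    "scoring_rule": "mean"
  }
]
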