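{
  "units": "mm",
  "sources": ["IS7454", "CPWD", "CCD", "ISO"],
  "rows": [
    {"requirement": "forward_high", "kind": "reach_min",
     "IS7454": [1350, 1600], "CPWD": 1200, "CCD": 1200, "ISO": 1200},
    {"requirement": "forward_low", "kind": "reach_min",
     "IS7454": null, "CPWD": 400, "CCD": 400, "ISO": 400},
    {"requirement": "forward_obstructed_high", "kind": "reach_min",
     "IS7454": [715, 830], "CPWD": 1100, "CCD": 1100, "ISO": null},
    {"requirement": "lateral_high", "kind": "reach_min",
     "IS7454": [1350, 1770], "CPWD": 1300, "CCD": 1300, "ISO": null},
    {"requirement": "lateral_low", "kind": "reach_min",
     "IS7454": null, "CPWD": 250, "CCD": 250, "ISO": null},
    {"requirement": "lateral_obstructed_high", "kind": "reach_min",
     "IS7454": null, "CPWD": 1200, "CCD": 1200, "ISO": null},
    {"requirement": "circular_turn_360", "kind": "turn_max",
     "IS7454": 1500, "CPWD": [1500, 2000], "CCD": 1800, "ISO": 1500}
  ]
}
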