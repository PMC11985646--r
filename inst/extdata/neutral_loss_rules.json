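{
  "comment": "Neutral-loss rule set for flavonoid glycosides and phenolics. nominal is the integer loss in Da; formula gives the lost residue composition where defined. Categories: sugar (glycosyl residues), acyl, small (ubiquitous small-molecule losses), cross_ring (partial C-glycoside sugar cleavages).",
  "rules": [
    {"name": "hexosyl",              "formula": "C6H10O5",  "nominal": 162, "category": "sugar"},
    {"name": "deoxyhexosyl",         "formula": "C6H10O4",  "nominal": 146, "category": "sugar"},
    {"name": "pentosyl",             "formula": "C5H8O4",   "nominal": 132, "category": "sugar"},
    {"name": "hexuronyl",            "formula": "C6H8O6",   "nominal": 176, "category": "sugar"},
    {"name": "deoxyhexosyl-hexosyl", "formula": "C12H20O9", "nominal": 308, "category": "sugar"},
    {"name": "coumaroyl",            "formula": "C9H6O2",   "nominal": 146, "category": "acyl"},
    {"name": "water",                "formula": "H2O",      "nominal": 18,  "category": "small"},
    {"name": "CO2",                  "formula": "CO2",      "nominal": 44,  "category": "small"},
    {"name": "CO",                   "formula": "CO",       "nominal": 28,  "category": "small"},
    {"name": "methyl",               "formula": "CH3",      "nominal": 15,  "category": "small"},
    {"name": "cross-ring-120",       "formula": "C4H8O4",   "nominal": 120, "category": "cross_ring"},
    {"name": "cross-ring-90",        "formula": "C3H6O3",   "nominal": 90,  "category": "cross_ring"}
  ]
}
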