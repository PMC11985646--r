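{
  "comment": "Curated aglycone library. diagnostic_fragments are nominal m/z observed in negative mode for the bare (deprotonated) aglycone. rda_a13 is the composition of the A-ring-containing product of the 1,3 retro-Diels-Alder cleavage (neutral form, H transfer included); null means no RDA prediction is defined for that scaffold. For flavonols a 1,4 cleavage is additionally predicted with the A-side neutral equal to rda_a13 minus CH2O.",
  "aglycones": [
    {"name": "quercetin",    "formula": "C15H10O7", "subclass": "flavonol",
     "diagnostic_fragments": [255, 193, 179, 151, 135, 121], "rda_a13": "C7H4O4"},
    {"name": "kaempferol",   "formula": "C15H10O6", "subclass": "flavonol",
     "diagnostic_fragments": [257, 135], "rda_a13": "C7H4O4"},
    {"name": "isorhamnetin", "formula": "C16H12O7", "subclass": "flavonol",
     "diagnostic_fragments": [300, 269, 151, 107], "rda_a13": "C7H4O4"},
    {"name": "syringetin",   "formula": "C17H14O8", "subclass": "flavonol",
     "diagnostic_fragments": [], "rda_a13": "C7H4O4"},
    {"name": "rhamnetin",    "formula": "C16H12O7", "subclass": "flavonol",
     "diagnostic_fragments": [], "rda_a13": "C8H6O4"},
    {"name": "kaempferide",  "formula": "C16H12O6", "subclass": "flavonol",
     "diagnostic_fragments": [], "rda_a13": "C7H4O4"},
    {"name": "luteolin",     "formula": "C15H10O6", "subclass": "flavone",
     "diagnostic_fragments": [257, 177, 151, 133, 107], "rda_a13": "C7H4O4"},
    {"name": "apigenin",     "formula": "C15H10O5", "subclass": "flavone",
     "diagnostic_fragments": [159, 151, 133, 117], "rda_a13": "C7H4O4"},
    {"name": "acacetin",     "formula": "C16H12O5", "subclass": "flavone",
     "diagnostic_fragments": [268, 151, 131], "rda_a13": "C7H4O4"},
    {"name": "baicalein",    "formula": "C15H10O5", "subclass": "flavone",
     "diagnostic_fragments": [117], "rda_a13": "C7H4O5"},
    {"name": "naringenin",   "formula": "C15H12O5", "subclass": "flavanone",
     "diagnostic_fragments": [225, 151, 136, 122, 119], "rda_a13": "C7H4O4"},
    {"name": "eriodictyol",  "formula": "C15H12O6", "subclass": "flavanone",
     "diagnostic_fragments": [213, 151, 135, 107], "rda_a13": "C7H4O4"},
    {"name": "hesperetin",   "formula": "C16H14O6", "subclass": "flavanone",
     "diagnostic_fragments": [286, 151, 134], "rda_a13": "C7H4O4"},
    {"name": "maritimetin",  "formula": "C15H10O6", "subclass": "aurone",
     "diagnostic_fragments": [], "rda_a13": null},
    {"name": "okanin",       "formula": "C15H12O6", "subclass": "chalcone",
     "diagnostic_fragments": [271, 179, 163, 153], "rda_a13": null}
  ]
}
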