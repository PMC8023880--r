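{
  "name": "kneealign-111",
  "version": "1.0",
  "comment": "Synthetic stand-in landmark schema for a standard AP knee radiograph outline (distal femur, patella, proximal tibia). The region layout is this package's own; it is NOT the proprietary ordering of any external landmark-search tool. Shaft polylines are ordered proximal to distal; condyle and plateau arcs run from the medial margin to the lateral margin; coordinates are image pixels (x right, y down) in canonical right-knee orientation (medial = +x).",
  "regions": [
    {"region": "fem_shaft_lateral", "n": 12},
    {"region": "fem_shaft_medial",  "n": 12},
    {"region": "fem_condyles",      "n": 24},
    {"region": "fem_notch_apex",    "n": 1},
    {"region": "patella",           "n": 20},
    {"region": "tib_plateau",       "n": 16},
    {"region": "tib_spine_base",    "n": 2},
    {"region": "tib_shaft_medial",  "n": 12},
    {"region": "tib_shaft_lateral", "n": 12}
  ]
}
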