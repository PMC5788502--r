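[
  {
    "id": "theophylline",
    "ligand": "theophylline",
    "sequence": "GGGGGCCCCCGCCCCC",
    "reference_structure": "((((((....))))))",
    "stem": [1, 6],
    "role": "sensor",
    "binding_bonus": 5,
    "note": "synthetic stand-in hairpin; placeholder for the theophylline aptamer, engineered for the package fold model"
  },
  {
    "id": "tetracycline",
    "ligand": "tetracycline",
    "sequence": "GGGCGCCCCCGCGCCC",
    "reference_structure": "((((((....))))))",
    "stem": [1, 6],
    "role": "sensor",
    "binding_bonus": 5,
    "note": "synthetic stand-in hairpin; placeholder for the tetracycline aptamer, engineered for the package fold model"
  },
  {
    "id": "eif4g",
    "ligand": "eif4g",
    "sequence": "CGGGGCCCCCGCCCCG",
    "reference_structure": "((((((....))))))",
    "stem": [1, 6],
    "role": "effector",
    "binding_bonus": 7,
    "note": "synthetic stand-in hairpin; placeholder for the eif4g aptamer, engineered for the package fold model"
  },
  {
    "id": "beta_catenin",
    "ligand": "beta_catenin",
    "sequence": "GCGGGCCCCCGCCCGC",
    "reference_structure": "((((((....))))))",
    "stem": [1, 6],
    "role": "sensor",
    "binding_bonus": 7,
    "note": "synthetic stand-in hairpin; placeholder for the beta_catenin aptamer, engineered for the package fold model"
  },
  {
    "id": "nfkb",
    "ligand": "nfkb",
    "sequence": "CCGGGCCCCCGCCCGG",
    "reference_structure": "((((((....))))))",
    "stem": [1, 6],
    "role": "sensor",
    "binding_bonus": 7,
    "note": "synthetic stand-in hairpin; placeholder for the nfkb aptamer, engineered for the package fold model"
  },
  {
    "id": "vegf",
    "ligand": "vegf",
    "sequence": "GCCGGCCCCCGCCGGC",
    "reference_structure": "((((((....))))))",
    "stem": [1, 6],
    "role": "sensor",
    "binding_bonus": 7,
    "note": "synthetic stand-in hairpin; placeholder for the vegf aptamer, engineered for the package fold model"
  },
  {
    "id": "opn",
    "ligand": "opn",
    "sequence": "CGGCGCCCCCGCGCCG",
    "reference_structure": "((((((....))))))",
    "stem": [1, 6],
    "role": "sensor",
    "binding_bonus": 7,
    "note": "synthetic stand-in hairpin; placeholder for the opn aptamer, engineered for the package fold model"
  }
]
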