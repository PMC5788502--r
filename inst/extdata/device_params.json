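{
  "theophylline_repressor": {
    "K": 300, "h": 1.3, "Emax_r": 0.9, "Fmax": 15, "kappa": 0.5,
    "note": "2x theophylline-aptamer roadblock repressor; K/h calibrated on the 0-1000 uM dose series (sub-saturating then saturating)"
  },
  "tetracycline_repressor": {
    "K": 20, "h": 1.3, "Emax_r": 0.9, "Fmax": 15, "kappa": 0.5,
    "note": "2x tetracycline-aptamer roadblock repressor; logic-high 100 uM"
  },
  "eif4g_activator_2x": {
    "K": 300, "h": 1.3, "Emax_r": 0, "Fmax": 15, "kappa": 0.5,
    "note": "2x eIF4G recruitment activator; Fmax calibrated from the saturating 15-fold reporter activation of the two-copy device"
  },
  "theophylline_switch_activator": {
    "K": 300, "h": 1.3, "Emax_r": 0, "Fmax": 15, "kappa": 0.5,
    "note": "theophylline-gated 2x eIF4G activator"
  },
  "tetracycline_switch_activator": {
    "K": 20, "h": 1.3, "Emax_r": 0, "Fmax": 15, "kappa": 0.5,
    "note": "tetracycline-gated 2x eIF4G activator"
  },
  "protein_sensor": {
    "K": 30, "h": 2, "Emax_r": 0.8, "Fmax": 3, "kappa": 0.5,
    "note": "protein-sensing connector (beta-catenin / NF-kB class) in arbitrary concentration units"
  },
  "opn_vegf_loop": {
    "K": 30, "h": 2, "Emax_r": 0.8, "Fmax": 3, "kappa": 0.5,
    "note": "edge parameters of the packaged OPN-VEGF feedback-loop models"
  }
}
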