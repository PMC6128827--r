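{
  "handle_bp": 510,
  "n_handles": 2,
  "dna": {
    "persistence_length": 45,
    "nm_per_bp": 0.338,
    "stretch_modulus": 1200
  },
  "peptide": {
    "persistence_length": 0.6,
    "nm_per_residue": 0.365
  },
  "helix_rise_nm_per_residue": 0.15,
  "kBT_pN_nm": 4.11,
  "chains": {
    "syx": [191, 268],
    "snap25": [2, 206],
    "syb": [2, 97]
  },
  "attachment": {
    "syx": 266,
    "syb": 97
  },
  "crosslink": {
    "syx": 202,
    "syb": 32
  },
  "state_axial_nm": {
    "fully_zippered": 0,
    "linker_open": 0.243827,
    "half_zippered": 0.897477,
    "unzipped": 3.609313,
    "snap25_off": 2.990455
  },
  "calibration": {
    "anchor_force_pN": 14,
    "anchors_nm": {
      "linker_open": 5.4,
      "half_zippered": 13.9,
      "unzipped": 26.7
    },
    "snap25_step_nm": 5,
    "snap25_step_force_pN": 16
  }
}
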