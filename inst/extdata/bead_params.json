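{
  "version": "1.0",
  "comment": "Toy coarse-grained bead parameters for the synthetic dendrimer-duplex models. Charges in e, lengths in Angstrom, energies in kcal/mol. These are representative bead-scale values, not force-field parameters.",
  "beads": {
    "PHO": {"q_prot": -1.0, "q_deprot": -1.0, "lj_sigma": 3.0, "lj_epsilon": 0.20, "radius": 2.4},
    "BAS": {"q_prot":  0.0, "q_deprot":  0.0, "lj_sigma": 3.0, "lj_epsilon": 0.15, "radius": 2.2},
    "MAJ": {"q_prot":  0.0, "q_deprot":  0.0, "lj_sigma": 2.8, "lj_epsilon": 0.10, "radius": 1.8},
    "MIN": {"q_prot":  0.0, "q_deprot":  0.0, "lj_sigma": 2.8, "lj_epsilon": 0.10, "radius": 1.8},
    "BCK": {"q_prot":  0.0, "q_deprot":  0.0, "lj_sigma": 3.0, "lj_epsilon": 0.15, "radius": 2.0},
    "AMN": {"q_prot":  1.0, "q_deprot":  0.0, "lj_sigma": 2.6, "lj_epsilon": 0.17, "radius": 1.9},
    "HYD": {"q_prot":  0.0, "q_deprot":  0.0, "lj_sigma": 3.2, "lj_epsilon": 0.25, "radius": 2.1}
  },
  "pka_intrinsic": {"ntr": 7.5, "lys_side": 10.4},
  "apolar": {"gamma": 0.00542, "beta": 0.92},
  "environment_field": {"eps_eff": 40.0, "cutoff": 12.0, "debye": 6.0},
  "site_coupling": {"eps_eff": 80.0, "cutoff": 12.0, "debye": 6.0}
}
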