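{
  "version": "1.0",
  "description": "Martini 3 coarse-grained parameters for hyaluronic acid and its monosaccharides. Units: k_b kJ/mol/nm^2, b0 nm, k_theta kJ/mol, theta0 deg, k_xi as printed (serialized verbatim; evaluated per GROMACS dihedral type 2 convention), xi0 deg, k_phi kJ/mol, phi0 deg.",
  "beads": [
    {"index": 1, "label": "T1", "martini_type": "P3r", "size": "T", "charge": 0, "residue": "GlcNAc", "group": "hydroxymethyl"},
    {"index": 2, "label": "T2", "martini_type": "N4r", "size": "T", "charge": 0, "residue": "GlcNAc", "group": "ring oxygen + anomeric carbon (+ anomeric OH at reducing end)"},
    {"index": 3, "label": "R3", "martini_type": "P2r", "size": "R", "charge": 0, "residue": "GlcNAc", "group": "ethanolamine"},
    {"index": 4, "label": "S4", "martini_type": "N4r", "size": "S", "charge": 0, "residue": "GlcNAc", "group": "hydroxyethyl"},
    {"index": 5, "label": "S5", "martini_type": "N5ar", "size": "S", "charge": 0, "residue": "GlcNAc", "group": "N-acetyl"},
    {"index": 6, "label": "S6", "martini_type": "Q5n", "size": "S", "charge": -1, "residue": "GlcA", "group": "carboxylate"},
    {"index": 7, "label": "T7", "martini_type": "N4r", "size": "T", "charge": 0, "residue": "GlcA", "group": "ring oxygen + anomeric carbon (+ anomeric OH at reducing end)"},
    {"index": 8, "label": "R8", "martini_type": "P3r", "size": "R", "charge": 0, "residue": "GlcA", "group": "vicinal diol"},
    {"index": 9, "label": "S9", "martini_type": "N4r", "size": "S", "charge": 0, "residue": "GlcA", "group": "oxyethyl"}
  ],
  "reducing_end_resize": {"2": "S", "7": "S"},
  "masses": {"T": 36, "S": 54, "R": 72},
  "glcnac": {
    "bonds": [
      {"i": 1, "j": 4, "k_b": 10700, "b0": 0.270},
      {"i": 2, "j": 3, "k_b": 19000, "b0": 0.284},
      {"i": 2, "j": 4, "k_b": 25000, "b0": 0.354},
      {"i": 3, "j": 4, "k_b": 19000, "b0": 0.288},
      {"i": 3, "j": 5, "k_b": 9500, "b0": 0.327},
      {"i": 4, "j": 5, "k_b": 10500, "b0": 0.631}
    ],
    "angles": [
      {"i": 1, "j": 4, "k": 2, "k_theta": 230, "theta0": 81, "form": "g96_cosine"},
      {"i": 1, "j": 4, "k": 3, "k_theta": 220, "theta0": 134, "form": "g96_cosine"},
      {"i": 5, "j": 3, "k": 2, "k_theta": 200, "theta0": 101, "form": "g96_cosine"}
    ],
    "impropers": [
      {"i": 4, "j": 3, "k": 2, "l": 1, "k_xi": 170, "xi0": 7.5},
      {"i": 3, "j": 4, "k": 2, "l": 5, "k_xi": 230, "xi0": -3.5}
    ]
  },
  "glca": {
    "bonds": [
      {"i": 6, "j": 9, "k_b": 14000, "b0": 0.250},
      {"i": 7, "j": 8, "k_b": 18000, "b0": 0.295},
      {"i": 7, "j": 9, "k_b": 24000, "b0": 0.357},
      {"i": 8, "j": 9, "k_b": 18000, "b0": 0.296}
    ],
    "angles": [
      {"i": 6, "j": 9, "k": 7, "k_theta": 420, "theta0": 86, "form": "g96_cosine"},
      {"i": 6, "j": 9, "k": 8, "k_theta": 250, "theta0": 137, "form": "g96_cosine"}
    ],
    "impropers": [
      {"i": 9, "j": 8, "k": 7, "l": 6, "k_xi": 300, "xi0": 10.5}
    ]
  },
  "chain": {
    "intra": {
      "bonds": [
        {"i": 1, "j": 4, "k_b": 11700, "b0": 0.274},
        {"i": 6, "j": 9, "k_b": 65000, "b0": 0.233},
        {"i": 2, "j": 3, "k_b": 73000, "b0": 0.232},
        {"i": 7, "j": 8, "k_b": 26000, "b0": 0.261},
        {"i": 2, "j": 4, "k_b": 36000, "b0": 0.289},
        {"i": 7, "j": 9, "k_b": 50000, "b0": 0.257},
        {"i": 3, "j": 4, "k_b": 42000, "b0": 0.284},
        {"i": 8, "j": 9, "k_b": 28000, "b0": 0.278},
        {"i": 3, "j": 5, "k_b": 38000, "b0": 0.330},
        {"i": 2, "j": 9, "k_b": 20000, "b0": 0.255},
        {"i": 4, "j": 5, "k_b": 3000, "b0": 0.615},
        {"i": 4, "j": 7, "k_b": 10000, "b0": 0.799}
      ],
      "angles": [
        {"i": 1, "j": 4, "k": 2, "k_theta": 345, "theta0": 78, "form": "g96_cosine"},
        {"i": 6, "j": 9, "k": 7, "k_theta": 630, "theta0": 93, "form": "g96_cosine"},
        {"i": 1, "j": 4, "k": 3, "k_theta": 270, "theta0": 126, "form": "g96_cosine"},
        {"i": 6, "j": 9, "k": 8, "k_theta": 345, "theta0": 146, "form": "restricted_bending"},
        {"i": 5, "j": 3, "k": 2, "k_theta": 500, "theta0": 126, "form": "g96_cosine"},
        {"i": 3, "j": 2, "k": 9, "k_theta": 150, "theta0": 93, "form": "g96_cosine"},
        {"i": 2, "j": 9, "k": 8, "k_theta": 150, "theta0": 116, "form": "g96_cosine"},
        {"i": 2, "j": 9, "k": 6, "k_theta": 150, "theta0": 80, "form": "g96_cosine"}
      ],
      "impropers": [
        {"i": 4, "j": 3, "k": 2, "l": 1, "k_xi": 150, "xi0": 16},
        {"i": 5, "j": 3, "k": 2, "l": 4, "k_xi": 170, "xi0": -173},
        {"i": 9, "j": 8, "k": 7, "l": 6, "k_xi": 350, "xi0": 13},
        {"i": 2, "j": 3, "k": 9, "l": 4, "k_xi": 170, "xi0": 5},
        {"i": 9, "j": 2, "k": 8, "l": 7, "k_xi": 300, "xi0": 13}
      ],
      "dihedrals": [
        {"i": 1, "j": 3, "k": 8, "l": 6, "k_phi": -32, "phi0": -138, "mult": 1}
      ]
    },
    "junction": {
      "bonds": [
        {"i": 7, "j": 12, "k_b": 400, "b0": 0.292},
        {"i": 7, "j": 11, "k_b": 5000, "b0": 0.473},
        {"i": 9, "j": 13, "k_b": 4000, "b0": 0.573},
        {"i": 2, "j": 12, "k_b": 5000, "b0": 0.802}
      ],
      "angles": [
        {"i": 8, "j": 7, "k": 12, "k_theta": 250, "theta0": 110, "form": "g96_cosine"},
        {"i": 7, "j": 12, "k": 11, "k_theta": 200, "theta0": 120, "form": "g96_cosine"},
        {"i": 7, "j": 12, "k": 13, "k_theta": 150, "theta0": 66, "form": "g96_cosine"}
      ],
      "impropers": [
        {"i": 7, "j": 8, "k": 9, "l": 12, "k_xi": 500, "xi0": 1},
        {"i": 12, "j": 11, "k": 13, "l": 7, "k_xi": 400, "xi0": -18}
      ],
      "dihedrals": [
        {"i": 8, "j": 7, "k": 12, "l": 11, "k_phi": -60, "phi0": -165, "mult": 1}
      ]
    }
  },
  "nonbonded": {
    "exclusion_depth": 1,
    "eps_r": 15,
    "cutoff_nm": 1.1,
    "pair_table_source": "martini3",
    "radii_nm": {"T": 0.191, "S": 0.230, "R": 0.264}
  },
  "timestep_ps": {"chain": 0.01, "monomer": 0.03}
}
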