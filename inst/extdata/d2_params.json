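{
  "comment": "Published D2 dispersion coefficients (C6 in J nm^6 mol^-1, van der Waals radii in Angstrom) for the elements of the silica/formamide system; s6 = 0.75 for the PBE functional, damping steepness d = 20.",
  "c6":    {"H": 0.14, "C": 1.75, "N": 1.23, "O": 0.70, "Si": 9.23},
  "r_vdw": {"H": 1.001, "C": 1.452, "N": 1.397, "O": 1.342, "Si": 1.716},
  "s6": 0.75,
  "d": 20,
  "cutoff": 30
}
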