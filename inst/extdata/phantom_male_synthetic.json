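{
  "name": "adult_male_synthetic",
  "sex": "male",
  "total_mass_kg": 73,
  "organ_masses_g": {
    "blood": 5600,
    "kidneys": 310,
    "liver": 1800,
    "spleen": 150,
    "small_intestine": 650,
    "lungs": 1200,
    "red_marrow": 1170,
    "muscle": 29000,
    "brain": 1450,
    "heart_wall": 330,
    "urinary_bladder_wall": 50
  },
  "_note": "Synthetic adult-male reference masses constructed for this package; physiologically plausible values, not a copy of any proprietary phantom."
}
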