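name: mfa_expt2
solid_species: MFA
solid_mass_g: 4.34
liquor_mass_g: 43.399999999999999
temperature_c: 25.0
liquor:
  diglyme-water: 0.82017982017982
  MFA: 0.140859140859141
  CBA: 0.011988011988012
  copper(II) acetate: 0.011988011988012
  2,3-dimethylaniline: 0.014985014985015
particles:
  mean_size_um: 94.0
  sphericity: 0.468
  x10_um: 39.030000000000001
  x50_um: 86.950000000000003
  x90_um: 176.47999999999999
  sd_um: 174.0
filter:
  diameter_mm: 27.0
  medium_resistance_per_m: 131000000.0
  equipment_volume_ml: 49.999999999999993
conditions:
  driving_force_mbar: 600.0
  temperature_c: 25.0
cake:
  porosity: 0.694
  sphericity: 0.526
  compressibility_index: 0.833
  reference_pressure_mbar: 1000.0
  alpha_ref: 51849547.718280702829361
wash_program:
- mechanism: displacement
  composition:
    diglyme-water: 0.13354262214069
    heptane: 0.86645737785931
  peclet: 10.0
  mode: accumulate
  wash_ratio: 2.0
- mechanism: displacement
  composition:
    heptane: 1.0
  peclet: 10.0
  mode: accumulate
  wash_ratio: 2.0
- mechanism: displacement
  composition:
    heptane: 1.0
  peclet: 10.0
  mode: accumulate
  wash_ratio: 2.0
provenance: 'MFA case study, experiment 2: diglyme-water / heptane, 600 mbar, wash
  ratio 2 x 3 washes; calibrated cake parameters of the matching solvent pair'
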