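pupil_diameter_mm: 6.7
wavelength_nm: 561.0
terms:
- 'n': 2
  m: 0
  coeff_um: 0.108528

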