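# Registry of synthetic phase-diagram scenarios: HU(alpha-alpha)-80bp DNA
# at four pH values and increasing NaCl, plus the E34K surface mutant.
# Lamellar scenarios carry the repeat spacing d (Angstrom) of the Bragg
# peak; filament scenarios are HU-saturated duplex Debye curves; aggregate
# scenarios are steep featureless decays. Seeds fix the noise realization.
scenarios:
  - {name: pH4.5_50mM,  expected_label: lamellar,  generator: lamellar,  d: 42, noise_frac: 0.01, seed: 101}
  - {name: pH4.5_100mM, expected_label: lamellar,  generator: lamellar,  d: 42, noise_frac: 0.01, seed: 102}
  - {name: pH4.5_150mM, expected_label: lamellar,  generator: lamellar,  d: 42, noise_frac: 0.01, seed: 103}
  - {name: pH4.5_300mM, expected_label: filament,  generator: filament,  noise_frac: 0.01, seed: 104}
  - {name: pH5.5_50mM,  expected_label: lamellar,  generator: lamellar,  d: 60, noise_frac: 0.01, seed: 105}
  - {name: pH5.5_100mM, expected_label: lamellar,  generator: lamellar,  d: 70, noise_frac: 0.01, seed: 106}
  - {name: pH5.5_150mM, expected_label: lamellar,  generator: lamellar,  d: 42, noise_frac: 0.01, seed: 107}
  - {name: pH5.5_300mM, expected_label: filament,  generator: filament,  noise_frac: 0.01, seed: 108}
  - {name: pH6.5_50mM,  expected_label: lamellar,  generator: lamellar,  d: 60, noise_frac: 0.01, seed: 109}
  - {name: pH6.5_150mM, expected_label: filament,  generator: filament,  noise_frac: 0.01, seed: 110}
  - {name: pH7.5_50mM,  expected_label: lamellar,  generator: lamellar,  d: 60, noise_frac: 0.01, seed: 111}
  - {name: pH7.5_150mM, expected_label: filament,  generator: filament,  noise_frac: 0.01, seed: 112}
  - {name: E34K_pH4.5,  expected_label: aggregate, generator: aggregate, noise_frac: 0.01, seed: 113}
  - {name: E34K_pH5.5,  expected_label: aggregate, generator: aggregate, noise_frac: 0.01, seed: 114}
  - {name: E34K_pH6.5,  expected_label: filament,  generator: filament,  noise_frac: 0.01, seed: 115}
  - {name: E34K_pH7.5,  expected_label: filament,  generator: filament,  noise_frac: 0.01, seed: 116}
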