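# Dense bilayer-center-referenced scheme: 37 windows, 0.1 nm spacing,
# Kf 1000 kJ/mol/nm^2, from the bilayer center (0.0) to bulk water (3.6).
reference_frame: bilayer_center
regions:
  - z_min: 0.0
    z_max: 3.6
    spacing: 0.1
    force_constant: 1000
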