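# Reduced monolayer-referenced scheme (reconstruction): 22 windows.
# 0.1 nm spacing with Kf 2000 in the hard-to-sample phosphate region
# (|z| <= 0.4 of the P layer); wider spacing and Kf <= 1000 elsewhere.
# z = 0 is the mean plane of the closest monolayer's P atoms; negative z
# is deeper insertion (z = -2.0 is near the membrane center).
# The water-side extent/spacing beyond +0.4 is a user choice; edit the
# last region to change it.
reference_frame: closest_p_layer
regions:
  - z_min: -2.0
    z_max: -0.6
    spacing: 0.2
    force_constant: 500
  - z_min: -0.4
    z_max: 0.4
    spacing: 0.1
    force_constant: 2000
  - z_min: 0.6
    z_max: 1.6
    spacing: 0.25
    force_constant: 1000
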