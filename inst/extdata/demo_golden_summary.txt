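frames: 12
mean twist: 36.02 deg
mean rise: 3.372 A
mean slide: -0.012 A
mean x-displacement: -0.003 A
mean inclination: -0.13 deg
mean roll: -0.08 deg
helix call: B
overall paired fraction: 0.8529
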