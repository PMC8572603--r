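# Default adult-arm configuration for the six-muscle planar elbow model.
# Units: metres, Newtons, degrees. Coordinates are in the elbow-centred
# frame (x anterior, y medial, z superior; forearm along -z at 0 deg).
# NOTE: r_0 (extensor moment arm at full extension) is not part of the
# anatomical tables the other values come from; 0.022 m is a representative
# adult value chosen for this demo fixture.
formula:
  gamma: 0.5
  A_s: 0.25
  f_M: 1.8
  v_max_factor: 8
  k_PE: 4
  eps0_M: 0.5
  k_s: 0.004
  A_nl: -1
  tendon_scale: 1.02
muscles:
  - name: biceps_long
    group: flexor
    l_mopt: 0.116
    l_topt: 0.272
    F_0: 624.3
    phi0_deg: 0
    origin: [0.023, 0.0, 0.115]
    insertion: [0.007, 0.0, -0.047]
    l_0: 0.263
  - name: biceps_short
    group: flexor
    l_mopt: 0.132
    l_topt: 0.192
    F_0: 435.6
    phi0_deg: 0
    origin: [0.023, 0.0, 0.115]
    insertion: [0.007, 0.0, -0.047]
    l_0: 0.178
  - name: brachialis
    group: flexor
    l_mopt: 0.086
    l_topt: 0.054
    F_0: 987.3
    phi0_deg: 0
    origin: [0.008, 0.0, 0.115]
    insertion: [0.007, 0.0, -0.023]
    l_0: 0.010
  - name: triceps_long
    group: extensor
    l_mopt: 0.134
    l_topt: 0.143
    F_0: 798.5
    phi0_deg: 12
    r_0: 0.022
  - name: triceps_lateral
    group: extensor
    l_mopt: 0.114
    l_topt: 0.091
    F_0: 624.3
    phi0_deg: 9
    r_0: 0.022
  - name: triceps_medial
    group: extensor
    l_mopt: 0.114
    l_topt: 0.098
    F_0: 624.3
    phi0_deg: 9
    r_0: 0.022
options:
  extensor_baseline: musculotendon
  literal_extensor_arc: false
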