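# SYNTHETIC two-muscle baseline fixture for the classic double-muscle
# elbow model. No anatomical table provides lumped parameters; these are
# constructed: the biceps line sums the two biceps-head forces and reuses
# the long-head path and lengths; the triceps line sums the three
# triceps-head forces on a posterior straight line to the olecranon, with
# l_0 chosen so the lumped fiber sits at its resting length at full
# extension. Units: metres, Newtons, degrees.
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
  - name: biceps
    group: flexor
    l_mopt: 0.116
    l_topt: 0.272
    F_0: 1059.9
    phi0_deg: 0
    origin: [0.023, 0.0, 0.115]
    insertion: [0.007, 0.0, -0.047]
    l_0: 0.263
  - name: triceps
    group: extensor
    l_mopt: 0.134
    l_topt: 0.143
    F_0: 2047.1
    phi0_deg: 12
    origin: [-0.020, 0.0, 0.115]
    insertion: [-0.022, 0.0, 0.010]
    l_0: 0.175
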