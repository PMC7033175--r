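# Example sensor configuration with explicit SI units in field names.
C_dl_farads: 1.0e-9
R_s_ohms: 10000
frequencies_hz: [300000, 500000, 1000000, 5000000, 20000000]
particles:
  bead:
    delta_R_ohms: 100
    radius_um: 1.4
  cell:
    delta_R_ohms: 800
    C_m_farads: 1.0e-10
    R_c_ohms: 400
    radius_um: 2.8
  aggregate:
    n_beads: 2
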