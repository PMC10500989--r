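#! FIELDS time cv_x cv_y U opes_main bias_total
#! SET min_cv_x -2.5
#! SET max_cv_x 2.5
 0.200000 -1.046721 1.021881 -9.903215 0.000000 0.000000
 0.400000 -0.981237 0.957214 -9.614332 0.512300 0.512300
# an interspersed comment line, as PLUMED restarts produce
 0.600000 -1.113412 1.094125 -9.701122 0.498121 0.498121
 0.800000 -0.893214 1.003127 -9.243119 1.021233 1.021233
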