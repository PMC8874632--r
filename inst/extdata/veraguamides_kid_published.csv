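molecule_id,homo,lumo,somo,hl_gap,j_i,j_a,j_hl,delta_sl
Veraguamide A,-6.635,-0.884,-0.892,5.751,0.006,0.003,0.006,0.003
Veraguamide B,-6.637,-0.942,-0.912,5.695,0.008,0.012,0.014,0.030
Veraguamide C,-6.812,-0.993,-0.946,5.819,0.003,0.017,0.017,0.048
Veraguamide D,-6.661,-0.748,-0.759,5.913,0.010,0.005,0.011,0.011
Veraguamide E,-6.873,-0.717,-0.702,6.156,0.002,0.007,0.007,0.014
Veraguamide F,-6.717,-1.016,-0.972,5.702,0.002,0.015,0.015,0.019
Veraguamide G,-6.697,-0.771,-0.768,5.926,0.009,0.001,0.009,0.003
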