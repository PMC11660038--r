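{"params":{"r_core":14,"r_outer":30,"rho_core":0.3,"rho_shell":0.36,"rho_solv":0.333,"poly_sigma":0,"scale_mic":2e-06,"f_mono":0,"rg_coil":15,"nu":0.5,"r_hs":30,"phi_hs":0.1,"background":0.001},"noise_frac":0.02,"seed":102}
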