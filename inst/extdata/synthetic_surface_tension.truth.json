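{"technique":"surface_tension","cmc":0.45,"pre_slope":-18,"post_slope":0,"response_at_cmc":41,"noise_sigma":0.4,"n":15,"conc_range":[0.05,2],"abscissa_transform":"log10","seed":101}
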