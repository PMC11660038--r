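{"S0":700,"S_inf":500,"tau":0.5,"ap":1.4,"noise_frac":0.01,"t_max":4,"dt":0.02,"seed":103}
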