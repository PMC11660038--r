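# technique: surface_tension, conc_unit: wt_percent
conc,response
0.05,58.04595057
0.06507330444,56.33755849
0.084690699,53.7868048
0.1102220728,52.0827347
0.14345029,50.06150719
0.1866956878,48.3469946
0.2429781066,46.06513261
0.316227766,43.71273152
0.4115597138,42.06484515
0.535631011,40.91069625
0.6971055969,41.21057924
0.9072592946,40.68206223
1.180767206,41.57110222
1.536728477,40.41327212
2,40.90532665
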