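# Post-annealing Tg and solubility limits, BDS, ambient pressure
temperature_K	tg_K	wtpct_drug	pressure_MPa	method
368	343	32	0.1	BDS
373	342	33	0.1	BDS
378	341	35	0.1	BDS
383	339	37	0.1	BDS
388	336	41	0.1	BDS
393	334	45	0.1	BDS
398	330	49	0.1	BDS
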