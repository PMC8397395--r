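# Post-annealing Tg and solubility limits, DSC, ambient pressure
temperature_K	tg_K	wtpct_drug	pressure_MPa	method
368	344	32	0.1	DSC
373	343	33	0.1	DSC
378	342	35	0.1	DSC
383	340	37	0.1	DSC
388	337	41	0.1	DSC
393	335	45	0.1	DSC
398	330	49	0.1	DSC
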