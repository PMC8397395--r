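# Post-annealing Tg and solubility limits, BDS, 50 MPa
temperature_K	tg_K	wtpct_drug	pressure_MPa	method
368	358	29	50	BDS
378	357	31	50	BDS
388	356	32	50	BDS
398	354	36	50	BDS
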