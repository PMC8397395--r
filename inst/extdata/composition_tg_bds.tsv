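# Dielectric (tau_alpha = 100 s) glass-transition temperatures of NMS + KVA mixtures, ambient pressure
wtpct_drug	tg_K	pressure_MPa	method
100	291	0.1	BDS
80	302	0.1	BDS
70	311	0.1	BDS
60	320	0.1	BDS
45	334	0.1	BDS
20	354	0.1	BDS
0	376	0.1	BDS
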