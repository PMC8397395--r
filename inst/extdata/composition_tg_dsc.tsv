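# Calorimetric glass-transition temperatures of NMS + KVA mixtures, ambient pressure
wtpct_drug	tg_K	pressure_MPa	method
100	294	0.1	DSC
80	303	0.1	DSC
70	312	0.1	DSC
60	321	0.1	DSC
45	335	0.1	DSC
20	355	0.1	DSC
0	377	0.1	DSC
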