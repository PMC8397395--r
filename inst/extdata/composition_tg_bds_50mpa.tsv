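# Dielectric glass-transition temperatures at 50 MPa
wtpct_drug	tg_K	pressure_MPa	method
80	314	50	BDS
60	332	50	BDS
45	346	50	BDS
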