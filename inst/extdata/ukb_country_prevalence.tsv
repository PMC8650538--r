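country	n	cad_prevalence_pct
England	317889	7.68
Scotland	31963	8.98
Wales	18724	8.30
NorthernIreland	2501	8.36
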