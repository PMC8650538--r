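country	n	mean	sd
England	317889	138.0	18.5
Scotland	31963	139.0	18.9
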