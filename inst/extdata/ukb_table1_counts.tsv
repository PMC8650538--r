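variable	level	england	scotland
gender	F	169679	17411
gender	M	148210	14552
antihypertensive	yes	72816	7577
antihypertensive	no	245073	24386
smoking	yes	32484	4078
smoking	no	285405	27885
diabetes	yes	24646	1918
diabetes	no	293243	30045
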