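row	frameshift	stop_gain
Singleton	39	1049
Common	8	49
Chinese	1	6
Indian	1	16
Cynomolgus	0	11
Chinese-Indian	2	4
Chinese-Cynomolgus	1	0
Indian-Cynomolgus	0	12
All	3	0
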