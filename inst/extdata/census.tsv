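population	N	G
Tubutulik	3100	5.43
Anvik	1700	5.48
Kogrukluk	12000	5.20
Koktuli	6000	5.13
BigSalmon	5000	5.65
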