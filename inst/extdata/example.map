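Chromosome	Position(bp)	Rate(cM/Mb)	Map(cM)
20	1	1.0	0.0
20	50001	2.0	0.05
20	100001	0.0	0.15
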