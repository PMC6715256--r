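pos	prev	nxt
5000	T	T
12000	A	A
18000	T	G
25000	A	T
33000	C	C
41000	T	G
52000	G	C
63000	C	T
74000	T	G
88000	T	A
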