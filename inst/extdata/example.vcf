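##fileformat=VCFv4.2
##contig=<ID=20,length=100000>
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	NA1	NA2	NA3	NA4
20	5000	.	A	G	.	PASS	.	GT	1|0	0|0	0|0	0|0
20	12000	.	T	C	.	PASS	.	GT	1|1	0|0	0|0	0|0
20	18000	.	C	T	.	PASS	.	GT	0|0	1|0	0|0	0|0
20	25000	.	G	C	.	PASS	.	GT	0|0	0|1	1|1	0|0
20	33000	.	A	T	.	PASS	.	GT	0|0	0|0	1|0	0|0
20	41000	.	C	A	.	PASS	.	GT	1|1	1|1	0|0	0|0
20	52000	.	T	A	.	PASS	.	GT	0|0	0|0	0|0	1|1
20	63000	.	G	A	.	PASS	.	GT	0|0	0|0	0|0	1|0
20	74000	.	A	C	.	PASS	.	GT	0|1	0|1	1|0	1|1
20	88000	.	C	T	.	PASS	.	GT	0|0	1|0	0|1	0|0
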