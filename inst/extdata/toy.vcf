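##fileformat=VCFv4.2
##source=handmade toy cohort for reader tests
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	S1	S2	S3	S4
1	101	rs1	A	G	.	PASS	.	GT	0/0	0/1	1/1	./.
1	205	rs2	C	T	.	PASS	.	GT	0|0	0|1	1|0	1|1
1	309	rs3	G	A,C	.	PASS	.	GT	0/1	0/2	1/2	0/0
2	150	rs4	T	C	.	PASS	.	GT	0/1	0/0	0/0	0/1
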