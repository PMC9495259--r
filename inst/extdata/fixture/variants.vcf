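##fileformat=VCFv4.2
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	RC1	RC2	RC3	RM1	RM2	RM3	HC1	HC2	HC3
1	1001	rs1000001	C	T	.	PASS	.	GT	1/1	1/1	1/1	0/0	0/0	0/0	0/0	0/0	0/0
2	1002	rs1000002	G	A	.	PASS	.	GT	0/1	0/1	0/0	0/0	0/0	0/0	0/0	0/0	0/0
3	1003	rs1000003	A	G	.	PASS	.	GT	0/1	0/1	0/1	0/1	0/1	0/0	0/0	0/0	0/0
4	1004	rs1000004	C	G	.	PASS	.	GT	1/1	1/1	1/1	0/0	0/0	0/0	0/0	0/0	0/0
5	1005	rs1000005	T	C	.	PASS	.	GT	0/1	0/1	0/1	0/1	0/0	0/0	0/0	0/0	0/0
6	1006	rs1000006	G	T	.	PASS	.	GT	1/1	1/1	1/1	0/0	0/0	0/0	0/1	0/0	0/0
7	1007	rs1000007	A	T	.	PASS	.	GT	0/1	0/0	0/0	0/1	0/0	0/0	0/0	0/0	0/0
8	1008	rs1000008	C	A	.	PASS	.	GT	0/0	0/0	0/0	0/1	0/1	0/1	0/0	0/0	0/0
9	1009	rs1000009	G	C	.	PASS	.	GT	1/1	1/1	1/1	0/0	0/0	0/0	0/0	0/0	0/0
10	1010	rs1000010	T	G	.	PASS	.	GT	0/1	0/0	0/0	0/0	0/0	0/0	1/1	1/1	0/0
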