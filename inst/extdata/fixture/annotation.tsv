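chrom	pos	ref	alt	gene	function_class	rsid
1	1001	C	T	G01	nonsynonymous_SNV	rs1000001
2	1002	G	A	G02	nonsynonymous_SNV	rs1000002
3	1003	A	G	G03	nonsynonymous_SNV	rs1000003
4	1004	C	G	G04	synonymous_SNV	rs1000004
5	1005	T	C	G05	stopgain	rs1000005
6	1006	G	T	G06	nonsynonymous_SNV	rs1000006
7	1007	A	T	G07	nonsynonymous_SNV	rs1000007
8	1008	C	A	G08	nonsynonymous_SNV	rs1000008
9	1009	G	C	G09	other	rs1000009
10	1010	T	G	G10	nonsynonymous_SNV	rs1000010
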