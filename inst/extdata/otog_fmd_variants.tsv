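contig	pos	ref	alt	rsid	consequence	cds_pos	gene_symbol	AF_NFE	AC_NFE	AN_NFE	AF_AFR	AC_AFR	AN_AFR	AF_EAS	AC_EAS	AN_EAS	AF_SAS	AC_SAS	AN_SAS	AF_AMR	AC_AMR	AN_AMR	AF_GLOBAL	AC_GLOBAL	AN_GLOBAL	cohort_ac	cohort_an
NC_000011.10	17553211	G	A	rs552304627	missense	421	OTOG	1.34E-3	.	113770	1.48E-4	.	16256	0	.	18394	8.88E-5	.	30616	1.87E-3	.	34592	8.80E-4	.	251496	1	200
NC_000011.10	17557227	G	A	rs61978648	missense	805	OTOG	4.43E-3	.	113770	6.28E-2	.	16256	0	.	18394	1.42E-3	.	30616	1.37E-2	.	34592	8.36E-3	.	251496	5	200
NC_000011.10	17599671	C	T	rs117005078	missense	3718	OTOG	5.55E-3	.	113770	8.81E-4	.	16256	0	.	18394	7.10E-4	.	30616	1.42E-3	.	34592	2.73E-3	.	251496	1	200
NC_000011.10	17606001	G	A	rs145689709	missense	4057	OTOG	4.08E-3	.	113770	4.43E-4	.	16256	0	.	18394	4.88E-4	.	30616	2.20E-3	.	34592	2.42E-3	.	251496	1	200
NC_000011.10	17610645	T	C	rs61744602	missense	5380	OTOG	3.59E-3	.	113770	1.47E-4	.	16256	0	.	18394	0	.	30616	1.02E-3	.	34592	1.63E-3	.	251496	1	200
NC_000011.10	17611118	C	T	rs748280789	missense	5854	OTOG	3.75E-5	.	113770	0	.	16256	0	.	18394	0	.	30616	0	.	34592	1.36E-5	.	251496	1	200
NC_000011.10	17611374	C	T	rs61736002	missense	6109	OTOG	1.24E-3	.	113770	4.45E-3	.	16256	9.34E-5	.	18394	4.74E-3	.	30616	4.88E-3	.	34592	2.47E-3	.	251496	5	200
NC_000011.10	17612217	G	A	rs188527711	missense	6214	OTOG	1.60E-3	.	113770	1.47E-4	.	16256	3.71E-4	.	18394	2.22E-4	.	30616	6.92E-4	.	34592	7.98E-4	.	251496	1	200
NC_000011.10	17635125	G	A	rs76461792	missense	7666	OTOG	4.89E-3	.	113770	1.56E-4	.	16256	0	.	18394	3.21E-3	.	30616	1.64E-3	.	34592	2.76E-3	.	251496	1	200
NC_000011.10	17638480	C	A	rs61995750	missense	7861	OTOG	2.01E-4	.	113770	1.56E-2	.	16256	0	.	18394	0	.	30616	9.78E-4	.	34592	9.84E-4	.	251496	1	200
NC_000011.10	17640936	C	T	rs567966154	missense	8071	OTOG	2.40E-4	.	113770	1.27E-2	.	16256	9.28E-5	.	18394	8.89E-5	.	30616	9.37E-4	.	34592	8.95E-4	.	251496	1	200
NC_000011.10	17641065	G	A	rs1310923563	missense	8200	OTOG	0	.	113770	0	.	16256	9.30E-5	.	18394	4.44E-5	.	30616	0	.	34592	1.39E-5	.	251496	1	200
NC_000011.10	17642200	G	A	rs117315845	missense	8404	OTOG	2.89E-3	.	113770	0	.	16256	9.28E-5	.	18394	2.62E-3	.	30616	2.57E-3	.	34592	2.61E-3	.	251496	2	200
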