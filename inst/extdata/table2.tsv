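chrom	pos	snp_id	located	nearest_genes	p	shap
1	218705814	rs1018040	Downstream	TGFB2/LYPLAL1	1.69E-05	0.017
1	152453338	rs11205009	Upstream	LCE5A	2.87E-06	0.010
3	15115369	rs1575081785	Missense	RBSN	4.98E-40	0.050
3	63389846	rs74707084	Intron	SYNPR	1.28E-65	0.049
3	29607405	rs1979271	Intron	RBMS3	2.44E-03	0.014
5	59757497	rs62372011	Intron	PDE4D	2.28E-10	0.013
6	57189167	rs17653532	Intron	PRIM2	1.18E-03	0.054
6	162119549	rs79275514	Intron	PARK2	8.30E-04	0.011
6	30901543	rs111474353	Upstream	DPCR1	6.08E-59	0.011
6	166147479	rs903439	Intron	PDE10A	1.31E-05	0.011
7	150095271	rs7393	UTR-3	ZNF775	9.72E-04	0.011
10	90178820	rs10887816	Intron	RNLS	1.72E-04	0.011
11	121787956	rs77119441	Downstream	SORL1	1.47E-16	0.016
12	33598920	rs12811317	Upstream	SYT10	1.66E-20	0.010
13	108050599	rs79219127	Intron	FAM155A	4.09E-33	0.015
13	25480913	rs201088712	Missense	CENPJ	3.49E-29	0.013
13	105888343	rs3015358	Downstream	DAOA-AS1	1.78E-03	0.010
14	87312206	rs114065456	Downstream	FLRT2/LINC01148	4.96E-32	0.015
15	25037506	rs4028683	Downstream	NPAP1	4.36E-03	0.010
18	55016814	rs75858984	Upstream	ST8SIA3	1.09E-24	0.017
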