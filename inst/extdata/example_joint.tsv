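MarkerName	Allele1	Allele2	Freq1	Effect	StdErr	IntEffect	IntStdErr	IntCor	Weight
rs186564	g	t	0.8472	0.0343	0.0167	-0.0191	0.0207	-0.4228	8000
rs632089	g	g	0.6969	-0.0698	0.0259	0.08	0.044	-0.3572	8000
rs227998	a	a	0.328	-4e-04	0.0178	-0.0026	0.0548	0.1224	8000
rs697163	t	c	0.3085	0.0396	0.0347	0.1274	0.034	-0.6186	8000
rs221241	c	a	0.6364	0.1578	0.0146	0.0688	0.0245	-0.0472	8000
rs153450	t	a	0.2286	-0.0957	0.0119	0.0431	0.0386	-0.3628	8000
rs232456	t	a	0.6189	0.0104	0.0174	0.014	0.0447	-0.6506	8000
rs884687	g	c	0.4496	0.0263	0.0341	0.1317	0.0598	-0.7867	8000
rs603379	t	c	0.3311	0.0535	0.0123	-0.0103	0.0412	-0.2937	8000
rs884211	a	a	0.6877	0.0511	0.0286	-0.1596	0.0304	-0.6327	7500
rs797785	a	g	0.3057	0.1552	0.0344	0.0572	0.0431	-0.6931	7800
rs356275	t	a	0.0823	-0.0444	0.0126	0.0393	0.0352	-0.0326	3000
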