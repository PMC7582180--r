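gene	chrom	start	width	n_probes	probe_ids	logfc	p	p_bh
GPR55	chr2	231790037	776	4	cg16382047;cg14254999;cg19827923;cg13531460	-0.45	5.1e-07	0.01
GPR55	chr2	231809610	87	3	cg08840017;cg25013095;cg21022949	-0.73	1.5e-08	0.0006
MAN1A1	chr6	119669112	260	4	cg03207915;cg08416875;cg02578070;cg19722656	-0.68	2.5e-08	0.0008
ESR1	chr6	152126895	1910	23	cg21157690;cg17264271;cg15543523;cg26089753;cg08884395;cg01715172;cg21608605;cg20627916;cg07671949;cg23164938;cg23165623;cg21614759;cg19411146;cg21950534;cg11813455;cg24900983;cg05171584;cg23467008;cg22839866;cg23009221;cg27316393;cg00655307;cg01777019	-0.36	3.6e-06	0.03
CDHR3	chr7	105515219	677	2	cg03619256;cg20186907	-0.55	7.8e-07	0.01
CDHR3	chr7	105518489	655	2	cg00494287;cg26780915	-0.68	3.6e-10	2.4e-05
NCOR2	chr12	124876433	217	3	cg16337430;cg16217368;cg11050793	-0.53	1.8e-06	0.02
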