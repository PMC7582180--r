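probe_id	chrom	pos	strand	gene	island_relation	enhancer	dhs	logfc	p	p_bh
cg06460587	chr6	31650930	-		Island	TRUE	FALSE	-1.38	3.75e-06	0.035
cg24531977	chr5	56204891	+	C5orf35	N_Shore	FALSE	FALSE	-1.14	2.46e-06	0.032
cg24690709	chr4	100768712	+	DAPP1	OpenSea	FALSE	FALSE	-1.03	6.73e-08	0.0029
cg26077005	chr6	27236793	+		OpenSea	FALSE	FALSE	-0.99	1.85e-07	0.0062
cg04853218	chr14	55769688	+	FBXO34	OpenSea	TRUE	FALSE	-0.94	1.01e-09	9.94e-05
cg08214808	chr11	45922166	-	MAPK8IP1	Island	FALSE	FALSE	-0.91	2.13e-06	0.031
cg11770323	chr13	80066032	+	NDFIP2	OpenSea	TRUE	FALSE	-0.90	4.18e-08	0.0020
cg21022949	chr2	231809697	+		OpenSea	FALSE	FALSE	-0.88	5.38e-07	0.011
cg07182616	chr14	33409812	+	NPAS3	OpenSea	FALSE	FALSE	-0.87	3.34e-06	0.034
cg13782615	chr11	4079556	+	STIM1	OpenSea	TRUE	FALSE	-0.86	2.48e-06	0.032
cg00726151	chr14	97881274	-		OpenSea	TRUE	FALSE	-0.80	3.26e-11	6.50e-06
cg06854264	chr1	200861254	+	C1orf106	S_Shore	TRUE	FALSE	-0.76	3.23e-06	0.034
cg03207915	chr6	119669112	+	MAN1A1	N_Shore	FALSE	FALSE	-0.76	2.57e-06	0.032
cg01436550	chr16	24781512	+	TNRC6A	OpenSea	TRUE	FALSE	-0.75	3.42e-06	0.034
cg12741231	chr8	19321936	-	CSGALNACT1	S_Shelf	FALSE	FALSE	-0.73	1.14e-10	1.51e-05
cg07343739	chrX	46617524	+	SLC9A7	N_Shore	TRUE	FALSE	-0.72	2.37e-06	0.032
cg05313153	chr8	119122430	+	EXT1	N_Shore	FALSE	FALSE	-0.71	3.92e-07	0.0097
cg07633835	chr10	5938186	-	FBXO18	OpenSea	TRUE	FALSE	-0.70	3.48e-06	0.034
cg25360385	chr12	51786547	-	GALNT6	S_Shore	FALSE	FALSE	-0.70	3.05e-06	0.034
cg19722656	chr6	119669372	-	MAN1A1	N_Shore	FALSE	FALSE	-0.67	1.01e-06	0.018
cg26780915	chr7	105519144	+		S_Shore	TRUE	FALSE	-0.66	1.25e-09	9.94e-05
cg03405260	chr17	77786344	+		Island	FALSE	FALSE	-0.65	5.10e-06	0.043
cg10900455	chr20	42545099	-	TOX2	Island	TRUE	FALSE	-0.65	7.91e-07	0.015
cg08416875	chr6	119669226	-	MAN1A1	N_Shore	FALSE	FALSE	-0.64	4.10e-06	0.037
cg13607082	chr12	122652224	-	LRRC43	OpenSea	FALSE	FALSE	-0.64	3.59e-07	0.0095
cg15447017	chr1	156095882	+	LMNA	OpenSea	FALSE	FALSE	-0.63	3.49e-07	0.0095
cg12454975	chrX	103356930	-	MCART6/ZCCHC18	N_Shore	TRUE	FALSE	-0.63	9.12e-07	0.017
cg08062822	chrX	103356845	-	MCART6/ZCCHC18	N_Shore	TRUE	FALSE	-0.62	2.49e-06	0.032
cg12186909	chr19	10533016	-	PDE4A	S_Shore	FALSE	FALSE	-0.57	3.10e-06	0.034
cg12589298	chr19	50828905	-	KCNC3	Island	FALSE	FALSE	-0.57	2.74e-06	0.033
cg07910680	chr18	56296449	+	ALPK2	OpenSea	TRUE	FALSE	-0.55	5.41e-06	0.044
cg08494390	chr4	87980297	-	AFF1	OpenSea	TRUE	FALSE	-0.54	5.90e-06	0.047
cg03403880	chr2	157255372	-		N_Shore	FALSE	FALSE	-0.52	2.66e-07	0.0081
cg14523284	chr5	131993614	-	IL13	S_Shore	FALSE	FALSE	-0.49	3.94e-06	0.036
cg02712553	chr10	64136038	-	ZNF365	S_Shore	FALSE	FALSE	-0.49	1.90e-06	0.029
cg17347326	chr17	77779426	+		S_Shore	TRUE	FALSE	-0.46	3.39e-08	0.0019
cg05649724	chr14	102415204	-		Island	FALSE	FALSE	-0.45	4.61e-07	0.010
cg16312212	chr8	18941574	+		OpenSea	TRUE	FALSE	3.23	1.73e-06	0.027
cg00211609	chr1	1178039	-	FAM132A	Island	FALSE	FALSE	1.26	5.28e-09	0.00035
cg04871131	chr7	94954202	+	PON1	S_Shore	TRUE	FALSE	1.01	1.09e-06	0.018
cg20595271	chr12	111889200	+	SH2B3	OpenSea	FALSE	FALSE	0.85	8.71e-08	0.0034
cg00839873	chr14	94421989	-	ASB2	OpenSea	FALSE	FALSE	0.77	3.64e-06	0.035
cg18482892	chr3	56833426	-	ARHGEF3	N_Shelf	FALSE	FALSE	0.73	4.46e-06	0.039
cg01956154	chr14	94423399	-	ASB2	OpenSea	TRUE	FALSE	0.71	5.00e-14	1.99e-08
cg26800893	chr11	67184596	-	ATPGD1	S_Shore	TRUE	FALSE	0.68	1.89e-07	0.0062
cg08943180	chr1	244516022	+	C1orf100	OpenSea	FALSE	FALSE	0.59	5.15e-06	0.043
cg05523877	chr10	72185663	+	EIF4EBP2	OpenSea	FALSE	FALSE	0.53	1.53e-06	0.025
cg01697865	chr11	117856007	+	IL10RA	N_Shore	FALSE	FALSE	0.53	5.23e-07	0.011
cg21786381	chr11	75234078	-	GDPD5	N_Shelf	FALSE	FALSE	0.48	3.11e-06	0.034
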