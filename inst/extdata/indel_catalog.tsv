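element	region	event_kind	interval_start	interval_end	length	bases
CsuPLE1.1	inside_orf	deletion	1415	1417	1	T
CsuPLE1.1	inside_orf	deletion	1531	1533	1	A
CsuPLE1.1	inside_orf	deletion	1735	1737	1	G
CsuPLE1.1	inside_orf	deletion	750	761	10	
CsuPLE1.1	inside_orf	deletion	1530	1533	2	AA
CsuPLE1.1	inside_orf	deletion	1606	1732	125	
CsuPLE1.1	inside_orf	deletion	2118	2128	9	
CsuPLE1.1	inside_orf	insertion	1532	1533	1	A
CsuPLE1.1	inside_orf	insertion	1798	1799	7	AGGTATA
CsuPLE1.1	outside_orf	deletion	49	51	1	A
CsuPLE1.1	outside_orf	deletion	50	52	1	T
CsuPLE1.1	outside_orf	deletion	77	79	1	T
CsuPLE1.1	outside_orf	deletion	556	558	1	A
CsuPLE1.1	outside_orf	deletion	2312	2314	1	T
CsuPLE1.1	outside_orf	deletion	79	91	11	
CsuPLE1.1	outside_orf	insertion	50	51	1	A
CsuPLE1.1	outside_orf	insertion	129	130	1	A
CsuPLE1.1	outside_orf	insertion	548	549	1	G
CsuPLE1.1	outside_orf	insertion	2313	2314	1	T
CsuPLE1.1	outside_orf	insertion	207	208	3	ACG
CsuPLE1.1	outside_orf	insertion	539	540	7	CCTGCCT
CsuPLE1.1	outside_orf	insertion	2313	2314	2	TT
CsuPLE1.1	outside_orf	insertion	2313	2314	3	TTT
CsuPLE1.1	outside_orf	insertion	2313	2314	2	TC
Csu-Ty3	inside_orf	deletion	1133	1135	1	G
Csu-Ty3	inside_orf	deletion	1389	1391	1	G
Csu-Ty3	inside_orf	deletion	1397	1399	1	T
Csu-Ty3	inside_orf	deletion	1646	1648	1	A
Csu-Ty3	inside_orf	deletion	1810	1812	1	T
Csu-Ty3	inside_orf	deletion	65	1029	963	
Csu-Ty3	inside_orf	deletion	1539	1567	27	
Csu-Ty3	inside_orf	insertion	272	273	1	C
Csu-Ty3	inside_orf	insertion	555	556	1	A
Csu-Ty3	inside_orf	insertion	576	577	1	G
Csu-Ty3	inside_orf	insertion	1852	1853	1	A
Csu-Ty3	inside_orf	insertion	896	897	4	TTCA
Csu-Ty3	inside_orf	insertion	1163	1164	4	TTAT
Csu-Ty3	inside_orf	insertion	1529	1530	30	
Csu-Ty3	outside_orf	deletion	47	49	1	A
Csu-Ty3	outside_orf	deletion	128	130	1	A
Csu-Ty3	outside_orf	deletion	729	731	1	A
Csu-Ty3	outside_orf	deletion	696	701	4	CTTT
Csu-Ty3	outside_orf	deletion	695	701	5	TCTTT
Csu-Ty3	outside_orf	insertion	19	20	1	A
Csu-Ty3	outside_orf	insertion	200	201	1	T
Csu-Ty3	outside_orf	insertion	139	140	5	TGTGA
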