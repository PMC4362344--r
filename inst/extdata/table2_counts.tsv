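taxon	A_elongata:rRNA	A_elongata:mRNA	Collozoum_sp:rRNA	Collozoum_sp:mRNA	S_streptacantha:rRNA	S_streptacantha:mRNA	A_scolymantha:rRNA	A_scolymantha:mRNA
alpha-Proteobacteria	2	7	1	47	5	30	8	19
beta-Proteobacteria	0	11	3	15	0	6	2	5
gamma-Proteobacteria	135	1645	16	242	53	1315	44	255
delta/epsilon-Proteobacteria	0	12	8	220	2	24	1	39
Unidentified Proteobacteria	0	45	0	139	0	121	0	130
Total Proteobacteria	137	1720	28	663	60	1496	55	448
Bacteroidetes	0	22	5	167	2	51	9	304
Planctomycetes	0	0	2	5	1	0	7	11
Cyanobacteria	1	0	0	32	1	20	1	21
Firmicutes	0	32	2	169	0	38	2	178
Actinobacteria	0	26	3	39	0	53	2	52
Chlamidiae	0	0	0	24	0	0	3	23
Unidentified bacteria	0	277	0	824	0	575	1	999
Other bacteria	0	0	2	20	1	21	5	6
Total bacteria	138	2077	42	1943	65	2254	85	2042
Acantharea	101	0	9	0	49	66	16	0
Cercozoa	32	0	2	0	119	0	28	7
Foraminifera	13	47	1	0	4	0	0	0
Polycystinea	12	0	10	0	521	0	2	0
Sticholonchida	10	0	1	0	7	0	0	0
Unclassified Rhizaria	3	7	2	100	93	66	1	103
Gromiidae	0	0	0	0	0	0	4	0
Total Rhizaria	171	54	25	100	793	132	51	110
Apicomplexa	12	37	2	231	3	48	3	289
Dinophyceae	3	35	45	43	3	0	20	15
Perkinsea	0	6	0	40	0	42	0	49
Ciliophora	7	82	1	278	9	108	0	305
Unidentified Alveolata	0	14	0	40	0	24	0	31
Total Alveolata	22	174	48	632	15	222	23	689
Blastocystae	0	10	0	13	0	15	0	25
Diatoms	7	66	4	100	4	66	3	103
Developayella	0	0	0	0	2	0	1	0
Dictyochophyceae	0	0	0	0	2	0	0	0
Labyrinthulida	0	0	0	0	0	0	4	20
Oomycetes	0	34	0	171	1	78	15	225
Pelagophyceae	0	77	0	122	0	137	0	217
PX clade	0	22	0	81	3	44	2	107
Synurophyceae	0	0	1	0	0	0	0	0
Unidentified Heterokonts	0	38	0	127	0	85	0	155
Total Heterokonts	7	247	5	614	12	425	25	852
Haptophyta	9	28	0	0	0	0	2	6
Cryptophyta	4	0	0	0	1	0	0	6
Excavata	0	65	17	261	1	78	0	269
Fungi	7	187	2	947	82	424	31	777
Hyphochytriomycetes	0	0	0	0	3	0	1	0
Metazoa	19	756	1	3101	42	2457	162	5730
Choanoflagellates	0	46	0	130	0	96	0	534
Unidentified Opisthokonta	0	346	0	1077	0	769	0	1675
Amoebozoa	2	64	0	209	0	84	2	578
Rhodophyta	2	0	0	0	0	0	0	0
Chlorophyta	2	91	2	0	31	137	1	2
Streptophyta	6	209	0	0	6	421	0	2
Unidentified Archaeoplastida	0	36	0	996	0	93	0	971
Total Archaeoplastida	10	336	2	996	37	651	1	975
Unidentified eukaryotes	19	2285	3	7040	134	4349	20	6523
Total eukaryotes	270	4588	103	15107	1120	9687	318	18724
Archea	0	0	0	0	0	0	0	11
Virus	0	0	0	10	0	29	0	12
No hits	0	5782	0	22583	0	10238	0	18303
Not assigned	0	1353	0	2988	0	1962	0	2754
Total	408	13800	145	42631	1185	24170	403	41846
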