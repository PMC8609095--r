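# Published homology table: thyroglobulin (Tg) vs CNS-expressed proteins.
# One row per homology segment; p_* = subject-protein span, a_* = Tg span.
# flags column transcribes the printed coincidence annotations verbatim,
# including the one segment (testican-3 17-95) whose printed flag is
# inconsistent with the reference segment coordinates.
autoantigen	grp	protein	accession	p_start	p_end	a_start	a_end	identity_pct	homology_pct	evalue	flags
TG	1	Nidogen-1 (entactin)	115298674	847	919	660	726	35	52	1.23e-5
TG	1	Nidogen-1 (entactin)	115298674	849	917	96	161	39	50	1.61e-5
TG	1	Nidogen-1 (entactin)	115298674	859	922	1015	1076	43	58	8.51e-7
TG	1	Nidogen-1 (entactin)	115298674	867	925	1159	1216	45	53	4.60e-4	Eno
TG	1	Nidogen-1 (entactin)	115298674	874	919	315	358	45	58	0.002
TG	1	Nidogen-1 (entactin)	115298674	880	919	882	921	35	52	0.281
TG	2	Testican-1	4759164	281	368	972	1062	29	46	6.03e-5
TG	2	Testican-1	4759164	312	385	298	367	37	52	2.42e-5	Eno
TG	2	Testican-1	4759164	313	372	96	155	35	51	0.001
TG	2	Testican-1	4759164	333	372	616	653	50	67	7.80e-5
TG	2	Testican-1	4759164	333	376	48	92	40	62	0.001
TG	3	Testican-2 (SPOCK2)	7662036	312	374	33	89	39	52	3.23e-4	AKRIAI
TG	3	Testican-2 (SPOCK2)	7662036	325	376	1019	1073	36	54	0.017
TG	3	Testican-2 (SPOCK2)	7662036	327	377	1160	1211	47	64	6.91e-5	Eno
TG	3	Testican-2 (SPOCK2)	7662036	332	376	615	658	47	63	2.19e-4
TG	3	Testican-2 (SPOCK2)	7662036	333	374	116	157	45	59	1.94e-4
TG	3	Testican-2 (SPOCK2)	7662036	333	374	315	355	50	66	5.24e-5
TG	4	SPARC-related modular calcium-binding protein 1 (SMOC-1)	11545873	54	149	50	151	28	40	0.034
TG	4	SPARC-related modular calcium-binding protein 1 (SMOC-1)	11545873	54	158	1106	1210	30	39	1.39e-4	Eno,AKRIAI
TG	4	SPARC-related modular calcium-binding protein 1 (SMOC-1)	11545873	95	149	34	83	41	54	2.69e-4	AKRIAI
TG	4	SPARC-related modular calcium-binding protein 1 (SMOC-1)	11545873	114	294	1027	1212	28	42	1.03e-9	Eno,AKRIAI
TG	4	SPARC-related modular calcium-binding protein 1 (SMOC-1)	11545873	116	292	181	358	25	39	8.360	Eno
TG	4	SPARC-related modular calcium-binding protein 1 (SMOC-1)	11545873	119	317	881	1110	26	38	1.73e-6	AKRIAI
TG	4	SPARC-related modular calcium-binding protein 1 (SMOC-1)	11545873	227	272	34	73	30	52	6.927	AKRIAI
TG	4	SPARC-related modular calcium-binding protein 1 (SMOC-1)	11545873	227	340	96	212	26	39	0.221
TG	4	SPARC-related modular calcium-binding protein 1 (SMOC-1)	11545873	239	295	609	661	40	54	0.031
TG	5	Testican-3	3581970	300	384	17	95	31	43	2.80e-4	Eno
TG	5	Testican-3	3581970	311	373	652	717	30	52	0.029
TG	5	Testican-3	3581970	317	376	96	155	38	46	9.63e-4
TG	5	Testican-3	3581970	318	372	999	1062	42	51	1.42e-5
TG	5	Testican-3	3581970	337	376	315	353	45	57	0.018
TG	5	Testican-3	3581970	337	376	616	653	42	62	0.005
TG	5	Testican-3	3581970	337	376	1165	1205	48	60	5.46e-4	Eno
TG	6	SPARC-related modular calcium-binding protein 2 (SMOC-2)	262050673	91	154	598	659	34	56	1.05e-5
TG	6	SPARC-related modular calcium-binding protein 2 (SMOC-2)	262050673	105	153	311	358	36	51	0.043
TG	6	SPARC-related modular calcium-binding protein 2 (SMOC-2)	262050673	109	156	116	163	39	52	0.002
TG	6	SPARC-related modular calcium-binding protein 2 (SMOC-2)	262050673	109	251	48	194	25	40	0.017
TG	6	SPARC-related modular calcium-binding protein 2 (SMOC-2)	262050673	109	301	1027	1230	28	43	4.21e-13	AKRIAI
TG	6	SPARC-related modular calcium-binding protein 2 (SMOC-2)	262050673	198	327	78	210	26	40	0.030
TG	6	SPARC-related modular calcium-binding protein 2 (SMOC-2)	262050673	233	295	613	672	33	50	0.012
TG	7	Insulin-like growth factor-binding protein 5 (IGFBP5)	10834982	210	265	611	660	33	51	0.033
TG	7	Insulin-like growth factor-binding protein 5 (IGFBP5)	10834982	215	253	315	348	41	56	0.581
TG	8	Signal peptide CUB and EGF-like domain-containing protein 1	120587029	636	752	1427	1532	29	36	0.106
TG	9	Ephrin type-B receptor 2	822606583	269	312	1473	1531	35	44	2.342
TG	10	Ephrin type-B receptor 6	294862532	311	335	1470	1494	48	60	6.469
TG	11	Ephrin type-A receptor 7	568599847	260	319	1457	1531	28	42	7.379
TG	12	Acetylcholinesterase	219518823	46	573	2211	2728	32	50	4.79e-66	AKRIAI,DDAHI
TG	13	Butyrylcholinesterase	1073548962	9	527	2204	2722	29	47	2.43e-61	AKRIAI,DDAHI
TG	14	Neuroligin-3	262359974	66	596	2225	2730	30	46	1.36e-52	AKRIAI,DDAHI
TG	15	Neuroligin-4 X-linked	24308209	70	539	2225	2671	29	48	2.60e-51	AKRIAI,DDAHI
TG	16	Neuroligin-4 Y-linked	256222771	70	539	2225	2671	29	48	2.98e-51	AKRIAI,DDAHI
TG	17	Neuroligin-1	1478051093	77	546	2225	2671	31	48	1.49e-49	AKRIAI,DDAHI
TG	18	Carboxylesterase 3 (CES3)	297747275	38	550	2204	2724	31	44	3.73e-49	AKRIAI,DDAHI
TG	19	Cocaine esterase	1463570077	35	526	2204	2722	29	45	2.57e-47	AKRIAI,DDAHI
TG	20	Carboxylesterase 5A	298231153	83	580	2225	2730	28	44	1.93e-42	AKRIAI,DDAHI
TG	21	Neuroligin-2	30840978	66	550	2225	2671	28	43	7.69e-42	AKRIAI,DDAHI
TG	22	Brain carboxylesterase hBr3	6009628	21	549	2197	2720	28	44	2.70e-40	AKRIAI,DDAHI
TG	23	Liver carboxylesterase 1	68508965	21	552	2197	2723	28	43	9.33e-40	AKRIAI,DDAHI
TG	24	KIAA1480 protein, partial	7959221	36	470	2298	2730	28	46	8.41e-39	AKRIAI,DDAHI
TG	25	Carboxylesterase 4A	1419235141	30	509	2203	2669	29	44	4.62e-37	AKRIAI,DDAHI
TG	26	Carboxylesterase 8 (CES8)	40555853	34	390	2318	2669	28	44	5.22e-24	AKRIAI,DDAHI
TG	27	KIAA1366 protein, partial	7243113	1	265	2409	2671	22	39	0.002	AKRIAI,DDAHI
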