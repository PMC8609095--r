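# Published homology table: TSH-R (P16473) vs CNS-expressed proteins.
# One row per homology segment; p_* = subject-protein span, a_* = TSH-R span.
# identity_pct / homology_pct as printed (homology = identical plus similar
# residues); flags = printed "coincidences with" column
# (Eno = alpha-enolase, AKRIAI, DDAHI), comma-separated.
autoantigen	grp	protein	accession	p_start	p_end	a_start	a_end	identity_pct	homology_pct	evalue	flags
TSHR	1	Leucine-rich repeat-containing G-protein coupled receptor 4 (LGR4)	157694513	20	253	20	252	24	39	1.19e-4	Eno,DDAHI
TSHR	1	Leucine-rich repeat-containing G-protein coupled receptor 4 (LGR4)	157694513	177	815	52	692	24	44	6.95e-45	Eno,AKRIAI,DDAHI
TSHR	2	Leucine-rich repeat-containing G-protein coupled receptor 5 (LGR5)	4504379	234	868	32	732	24	42	1.25e-43	Eno,AKRIAI,DDAHI
TSHR	3	Relaxin receptor 2 (LGR8)	18677729	115	708	29	695	22	40	7.82e-29	Eno,AKRIAI,DDAHI
TSHR	4	Relaxin receptor 1 (LGR7)	359279868	182	738	182	710	25	44	1.75e-34	Eno,AKRIAI,DDAHI
TSHR	5	Chondroadherin	153251229	24	219	28	250	21	44	0.013	Eno,DDAHI
TSHR	6	LINGO2	22749183	26	205	22	254	25	43	0.028	Eno,DDAHI
TSHR	7	Somatostatin receptor type 2	4557859	24	322	395	688	23	41	1.14e-9	Eno,AKRIAI
TSHR	8	Neuropeptide Y receptor type 1	4505445	50	331	424	689	24	41	2.07e-8	Eno,AKRIAI
TSHR	9	Apelin receptor	4885057	38	318	424	687	25	42	2.78e-8	Eno,AKRIAI
TSHR	10	Neuromedin-K receptor (tachykinin receptor 3)	7669548	84	382	418	696	26	43	4.26e-8	Eno,AKRIAI
TSHR	11	Free fatty acid receptor 3	4885329	88	334	494	731	20	41	5.11e-7	Eno,AKRIAI
TSHR	12	Melanopsin (opsin-4)	15150803	73	386	417	710	22	36	1.60e-6	Eno,AKRIAI
TSHR	13	G-protein coupled estrogen receptor 1	4504091	68	332	423	686	23	41	5.02e-6	Eno,AKRIAI
TSHR	14	Alpha-1A adrenergic receptor	111118992	9	354	393	706	20	38	1.71e-5	Eno,AKRIAI
TSHR	15	Vasopressin V1a receptor	4502331	64	358	427	688	21	39	3.46e-5	Eno,AKRIAI
TSHR	16	Probable G-protein coupled receptor 34	4885319	26	367	370	727	19	40	3.86e-5	Eno,AKRIAI
TSHR	17	G-protein coupled receptor 26	23592220	79	200	494	609	26	47	7.64e-5	Eno,AKRIAI
TSHR	18	Orexin 2 receptor	1285033761	71	163	424	523	28	50	8.46e-5
TSHR	19	Oxytocin receptor	32307152	56	357	431	711	23	40	1.28e-4	Eno,AKRIAI
TSHR	20	Orexin receptor type 1	222080095	63	169	431	546	28	44	4.14e-4
TSHR	21	Galanin receptor type 2	4503905	37	302	426	688	22	39	6.07e-4	Eno,AKRIAI
TSHR	22	GPER protein	52350636	68	274	423	639	24	42	6.90e-4	Eno,AKRIAI
TSHR	23	N/OFQ opioid receptor	385252102	135	401	424	686	22	41	0.002	Eno,AKRIAI
TSHR	24	Type 2 angiotensin II receptor	23238240	103	350	481	707	24	41	0.002	Eno,AKRIAI
TSHR	25	Alpha-1B adrenergic receptor	4501959	57	357	426	687	19	37	0.006	Eno,AKRIAI
TSHR	26	Mu opioid receptor	119568090	142	453	424	744	20	39	0.011	Eno,AKRIAI
TSHR	27	Melanin-concentrating hormone receptor 1	397487122	119	393	424	691	22	40	0.013	Eno,AKRIAI
TSHR	28	Bombesin receptor subtype-3	4502455	60	339	427	687	19	40	0.023	Eno,AKRIAI
TSHR	29	Neuropeptide Y receptor type 5	5453796	5	93	381	466	27	50	0.029	AKRIAI
TSHR	30	C3a anaphylatoxin chemotactic receptor	4757888	331	444	576	687	22	44	0.151	AKRIAI
TSHR	31	Substance-P receptor (tachykinin receptor 1)	4507343	54	163	436	554	25	41	0.365
TSHR	32	Proteinase-activated receptor 2	34577052	77	352	416	686	21	39	0.394	Eno,AKRIAI
TSHR	33	Trace amine-associated receptor 6 (TaR-6)	28173558	35	135	417	524	30	53	0.463
TSHR	34	Urotensin-2 receptor (G-protein coupled receptor 14)	9506745	115	323	487	686	23	42	0.515	Eno,AKRIAI
TSHR	35	Nociceptin receptor	974065167	132	322	508	686	25	44	0.779	Eno,AKRIAI
TSHR	36	G-protein coupled receptor 24	56554976	149	267	584	691	24	47	0.812	AKRIAI
TSHR	37	C-C chemokine receptor type 7	4502641	320	374	672	725	29	49	0.941
TSHR	38	Olfactory receptor 2A14	48717236	96	164	494	562	30	47	1.001
TSHR	39	Vasopressin V2 receptor	4557345	267	326	620	679	30	45	1.119	AKRIAI
TSHR	40	Neuropeptide S receptor	46395496	54	336	419	684	21	42	1.139	Eno,AKRIAI
TSHR	41	Trace amine-associated receptor 8 (TaR-8)	16751917	40	100	423	483	38	60	1.342
TSHR	42	Neuropeptides B/W receptor type 2	30581164	58	326	427	688	24	41	2.476	Eno,AKRIAI
TSHR	43	Olfactory receptor 2 J3	185134902	39	156	426	550	24	44	2.929
TSHR	44	G protein-coupled receptor	953233	299	318	670	689	55	75	7.670
TSHR	45	Oxoglutarate (alpha-ketoglutarate) receptor 1	52426789	18	313	402	689	23	38	7.822	Eno,AKRIAI
TSHR	46	5-hydroxytryptamine receptor 7 (5-HT7)	10880129	111	389	445	683	20	36	8.232	Eno,AKRIAI
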