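# Published linear epitopes on the thyroid autoantigens and on CNS
# proteins from the homology tables (protein_id = GI accession for CNS
# proteins). modification notes post-translational variants of the
# epitope peptide; empty = unmodified.
protein_id	name	start	end	modification
TG	Tg epitope 20-190	20	190
TG	Tg epitope 1116-1168	1116	1168
TG	Tg epitope 1168-1269	1168	1269
TG	Tg epitope 1473-1526	1473	1526
TSHR	TSH-R immunogenic region 441-661	441	661
TPO	TPO epitope 766-775	766	775
TPO	TPO epitope 842-861	842	861
115298674	nidogen-1 epitope 867-887	867	887
822606583	ephrin type-B receptor 2 epitope 309-318	309	318
311033452	fibrillin-1 epitope 733-748	733	748	citrullinated in R11
311033452	fibrillin-1 epitope 737-752	737	752	citrullinated in R7
311033452	fibrillin-1 epitope 917-932	917	932	citrullinated in R14
311033452	fibrillin-1 epitope 921-936	921	936	citrullinated in R10
311033452	fibrillin-1 epitope 925-940	925	940	citrullinated in R6
311033452	fibrillin-1 epitope 947-955	947	955	cysteinylated in C4
311033452	fibrillin-1 epitope 1186-1194	1186	1194
311033452	fibrillin-1 epitope 1203-1211	1203	1211	methylated in C6
311033452	fibrillin-1 epitope 1256-1264	1256	1264	methylated in C8
311033452	fibrillin-1 epitope 1689-1697	1689	1697	methylated in C7
311033452	fibrillin-1 epitope 2301-2316	2301	2316	citrullinated in R6 and R11
311033452	fibrillin-1 epitope 2305-2320	2305	2320	citrullinated in R2 and R7
311033452	fibrillin-1 epitope 2309-2324	2309	2324	citrullinated in R3
311033452	fibrillin-1 epitope 2502-2510	2502	2510	methylated in C8
56237021	fibrillin-3 epitope 594-602	594	602
56237021	fibrillin-3 epitope 773-786	773	786
56237021	fibrillin-3 epitope 878-886	878	886
56237021	fibrillin-3 epitope 2425-2440	2425	2440	citrullinated in R9
56237021	fibrillin-3 epitope 2429-2444	2429	2444	citrullinated in R5 and R14
126012573	LRP-2 epitope 1397-1412	1397	1412	citrullinated in R12 and R16
126012573	LRP-2 epitope 1401-1416	1401	1416	citrullinated in R8 and R12
157384998	LRP-4 epitope 361-376	361	376	citrullinated in R13
157384998	LRP-4 epitope 365-380	365	380	citrullinated in R9
397487122	MCHR1 minor epitope 51-80	51	80
397487122	MCHR1 major epitope 85-98	85	98
397487122	MCHR1 minor epitope 154-158	154	158
397487122	MCHR1 major function-blocking epitope 254-260	254	260
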