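# Autoantigen spans previously reported homologous to the three
# encephalopathy autoantigens: alpha-enolase (Eno), aldo-keto reductase
# family 1 member A1 (AKRIAI) and dimethylargininase-I (DDAHI).
# counterpart_* = the matching span on the encephalopathy autoantigen.
autoantigen	start	end	source	counterpart_start	counterpart_end
TSHR	149	161	Eno	40	52
TSHR	560	575	Eno	284	299
TSHR	360	415	AKRIAI	89	141
TSHR	396	402	AKRIAI	258	264
TSHR	555	563	AKRIAI	14	22
TSHR	620	676	AKRIAI	268	325
TSHR	141	148	DDAHI	242	249
TSHR	263	292	DDAHI	258	283
TG	298	329	Eno	18	48
TG	1171	1186	Eno	208	223
TG	1315	1337	Eno	375	395
TG	1368	1385	Eno	280	297
TG	31	90	AKRIAI	178	227
TG	1086	1114	AKRIAI	111	140
TG	1107	1129	AKRIAI	6	26
TG	2612	2668	AKRIAI	86	124
TG	1597	1612	DDAHI	64	81
TG	2277	2286	DDAHI	218	227
TG	2605	2617	DDAHI	230	242
TPO	603	627	Eno	261	281
TPO	609	623	Eno	227	241
TPO	637	659	Eno	211	233
TPO	700	722	Eno	243	265
TPO	710	721	Eno	346	357
TPO	333	369	AKRIAI	282	324
TPO	410	456	AKRIAI	22	72
TPO	421	428	AKRIAI	289	296
TPO	535	552	AKRIAI	169	186
TPO	492	566	DDAHI	10	77
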