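transcript_id	PM	PG1	PG5	S2	S3	S4	cv_published	mean_rpmm_published	best_hit	description
rp11_olive_006695	205	209	206	208	177	154	10.72	193.2	Q39011	Shaggy-related protein kinase eta
rp11_olive_000781	105	140	112	104	108	127	11.36	116	Q94A41	Alpha-amylase 3, chloroplastic
rp11_olive_006061	327	272	238	343	285	253	13.16	286.3	Q8VZ80	Polyol transporter 5
rp11_olive_006091	283	221	211	208	177	190	15.65	215	A0A022R151	Uncharacterized protein
rp11_olive_010107	228	213	184	250	295	199	15.98	228.2	O23254	Serine hydroxymethyltransferase 4
rp11_olive_005197_split_1	366	430	381	343	423	552	16.37	415.8	Q42679	S-adenosylmethionine decarboxylase proenzyme
rp11_olive_003279	122	179	153	114	118	145	16.64	138.5	Q9LV37	Mitogen-activated protein kinase 9
rp11_olive_000623	94	94	58	104	108	100	17.68	93	A0A068V6W8	Genomic scaffold protein
rp11_olive_007981	144	149	108	156	147	91	18.2	132.5	Q93Y40	Oxysterol-binding protein-related protein 3C
rp11_olive_005099	888	728	678	530	550	579	18.84	658.8	P53492	Actin-7
rp11_olive_005815	311	272	256	322	364	444	19.03	328.2	P17598	Catalase isozyme 1
rp11_olive_000209_split_1	161	115	117	166	118	100	19.16	129.5	Q67YI9	Clathrin interactor EPSIN 2
rp11_olive_001245	161	175	108	166	187	118	19.16	152.5	A5A7I7	Calcium-dependent protein kinase 4
rp11_olive_008079	239	204	197	343	275	263	19.34	253.5	M1AVD3	Uncharacterized protein
rp11_olive_008883	128	119	144	187	108	118	19.51	134	Q9LZI2	UDP-glucuronic acid decarboxylase 2
rp11_olive_035033	178	166	224	177	285	199	19.76	204.8	P62201	Calmodulin
rp11_olive_029725	211	128	184	177	157	118	19.82	162.5	O04834	GTP-binding protein SAR1A
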