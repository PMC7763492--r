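sample_id	star_mapped_reads	rna_total_reads	rna_unique_clonotypes	rna_singletons	ir_total_reads	ir_unique_clonotypes	ir_singletons
MM_1	54357923	820	431	299	4050594	90068	63126
MM_10	48374912	826	504	403	7293770	250572	199844
MM_19	56698751	819	331	250	10073447	275520	252410
MM_29	59981954	85	65	54	7761188	272594	272079
MM_31	51623766	659	331	241	8120860	403438	373784
MM_34	48536509	1245	809	649	8836571	821579	688017
MM_35	49161059	1195	883	697	8039194	423108	366790
MM_36	43189398	652	416	323	9918279	555803	521536
MM_37	52095895	827	613	510	6500208	487124	425707
MM_38	49316301	258	165	124	8195923	408764	378106
MM_39	48288693	716	412	338	9833228	431722	396254
MM_4	34559031	615	451	348	8126107	602704	557693
MM_40	45488936	499	289	198	9963987	127280	105512
MM_41	42258878	202	104	71	8761312	90503	86489
MM_42	45563654	340	120	78	7180034	91962	78633
MM_44	53663728	693	470	371	8595247	281018	200700
MM_46	47093079	408	118	72	8958694	360441	348835
MM_47	46913279	477	299	237	10274849	254130	202285
MM_48	45465437	933	403	308	9565796	559857	501017
MM_49	50302951	628	300	215	9402588	416450	381187
MM_5	46521960	248	141	97	7732378	347955	345460
MM_50	41180449	392	304	250	7324348	176306	126269
MM_6	52868514	1177	879	712	10053037	1007123	866380
MM_61	41841298	136	71	54	4765448	96738	91318
MM_66	37559665	503	346	259	7836149	205940	163488
MM_67	41723673	904	329	213	6478122	129689	99656
MM_68	45666045	495	313	209	9016842	203599	146692
MM_7	57602270	1273	912	718	9700140	749213	664845
MM_70	36073087	447	267	199	7430562	210866	154254
MM_71	47691240	1158	591	412	8943282	204495	141742
MM_72	38540649	306	203	156	6900306	135644	114276
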