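feature_id	S001	S002	S003	S004	S005	S006	S007	S008	S009	S010	S011	S012	S013	S014	S015	S016	S017	S018	S019	S020	S021	S022	S023	S024	S025	S026	S027	S028	S029	S030	S031	S032	S033	S034	S035	S036	S037	S038	S039	S040
OTU_0001	692	164	984	864	196	667	282	733	500	174	985	684	1499	369	1659	1506	2397	4165	244	1570	355	122	97	154	564	82	201	220	781	213	258	295	227	168	160	106	432	117	1023	191
OTU_0002	1278	2604	389	536	194	518	214	319	181	2154	195	447	670	837	268	305	335	155	233	417	283	808	1036	2133	1167	1804	1359	2633	1151	882	919	629	620	783	11024	1477	1136	1861	734	933
OTU_0003	487	885	497	237	304	243	219	283	129	1072	574	465	907	783	38	627	683	254	127	582	172	336	1011	3228	749	1256	711	1876	1852	1047	155	933	1268	2592	1891	2062	772	1123	588	620
OTU_0004	161	642	388	262	1515	741	2723	6031	404	1311	524	90	2131	286	690	2576	875	199	33	132	353	325	145	85	359	1730	83	175	191	13	37	39	363	4054	465	467	535	286	57	233
OTU_0005	1	4	26	47	8	20	332	42	3	2	19	43	5	4	8	506	114	29	308	22	7	50	21	28	26	12	25	604	82	176	11	52	5	48	15	13	257	24	57	23
OTU_0006	1247	17	343	286	168	87	44	156	356	625	451	30	14	96	470	1605	71	689	3479	158	2833	488	7007	467	295	145	998	2570	431	2328	635	4	974	183	113	118	720	145	472	316
OTU_0007	71	151	38	6	242	957	886	27	192	220	1234	40	196	184	8	31	31	75	28	156	130	21	161	48	17	60	58	183	46	36	32	59	20	32	12	15	166	90	39	97
OTU_0008	156	100	6	42	22	15	132	78	24	51	12	36	42	596	874	352	103	347	44	24	107	1584	53	545	771	147	87	82	422	39	455	22	114	145	177	90	255	47	1680	100
OTU_0009	93	714	1818	164	6685	231	316	5764	559	745	1411	1045	4092	620	1137	977	428	172	253	312	155	28851	124	819	230	205	819	442	225	3180	47	1033	1127	1869	209	910	33	165	53	1014
OTU_0010	156	2059	1675	1198	881	970	9421	170	78	130944	152	2747	532	1319	44	42	3368	373	449	619	1501	722	375	3563	591	408	208	2476	3095	1012	1158	163	1111	519	854	1001	621	581	841	1323
OTU_0011	83	99	3	16	53	54	13	23	84	208	8	126	41	108	158	99	180	32	135	17	21	15	16	60	16	39	20	43	144	84	91	15	76	44	84	7	37	2	16	438
OTU_0012	2975	56	52	148	299	47	110	2975	300	1017	19019	22	420	151	154	225	471	13	159	134	199	48	928	101	121	130	305	40	127	541	826	966	367	139	240	268	1078	122	1833	15
OTU_0013	359	96	157	272	210	242	57	21	1213	36	38	21	74	491	25	1176	290	544	7	71	105	1036	1238	65	89	69	1084	81	67	26	31	17	1460	28	224	44	41	19	340	331
OTU_0014	90	253	957	127	773	234	349	793	81	842	5759	253	786	47	528	1340	90	123	1173	1343	2689	299	5093	3879	1985	1549	468	756	1747	84	238	411	571	359	495	512	434	836	873	864
OTU_0015	603	107	826	66	240	432	67	1918	32	135	72	7696	105	131	567	88	197	67	774	76	78	270	189	1176	83	1126	108	1072	180	1420	169	300	2592	323	381	635	45	1394	56	247
OTU_0016	242	693	2557	3917	889	205	1164	447	2638	506	247	853	3251	619	508	2444	917	584	2750	74	229	1307	782	4893	11959	2360	493	1143	354	631	1546	526	197	316	306	327	187	372	329	142
OTU_0017	235	439	807	269	10329	311	297	141	896	30	25	25545	202	1555	2827	127	2691	164	1306	611	66	560	764	1072	3445	510	246	904	6063	180	374	1605	1480	262	321	357	215	275	616	9546
OTU_0018	99	86	52	22	322	257	58	12	13	59	152	63	85	25	102	103	12	42	127	18	888	43	55	15	55	45	9	2	176	350	7	127	23	55	106	293	6	48	262	176
OTU_0019	616	85	1145	9	43	64	17	7831	172	179	98	17	215	890	334	118	359	574	278	157	432	1027	4597	60	33	32	69	398	788	3137	104	140	254	2	39	55	114	518	381	67
OTU_0020	140	171	27	266	671	145	373	249	498	726	534	569	1372	130	43	169	338	81	1111	239	2863	5509	44	136	52	560	26	1048	166	760	2592	483	1006	786	5081	174	161	698	213	432
OTU_0021	2425	3576	5955	3075	313	1408	3960	709	6438	321	515	178	2102	1973	803	6106	3337	228	2358	595	933	3182	2089	782	6009	2270	8580	3110	872	99	996	1194	619	5091	8112	1854	1069	2984	358	7358
OTU_0022	118	119	8	17	7	972	202	172	5	44	106	8	32	86	46	17	367	14	9	564	3	121	11	54	1	49	59	50	111	2	104	29	17	199	17	34	48	12	106	11
OTU_0023	143	48	263	338	154	841	1098	2628	419	118	759	1608	124	545	36	783	187	190	189	613	57	837	297	382	3494	87	1440	356	3268	393	320	111	26	185	2126	2634	2151	770	1213	272
OTU_0024	678	1278	375	885	783	3313	2684	696	397	959	103	2627	1303	429	246	6356	8447	281	261	464	233	998	44	1599	250	4175	1048	6012	590	504	190	3851	253	706	983	985	927	205	270	219
OTU_0025	28	30	122	17	106	277	13	33	99	19	30	286	47	83	7	120	23	36	278	329	58	16	31	42	57	10	56	28	159	1038	31	40	50	10	306	16	231	277	83	39
OTU_0026	5561	1900	1999	8995	1070	4586	1533	137	199	6891	25	2682	253	4282	1480	2093	554	1404	40	484	107	3587	8046	74	2989	268	283	383	7285	77	195	1167	951	320	127	493	1195	234	148	541
OTU_0027	162	2381	210	2863	127	154	3031	149	3053	148	173	41	59	1164	933	9162	2980	81	230	84	4202	432	5709	743	202	1710	1935	251	376	69	1920	132	4248	641	149	2629	1078	1037	908	1432
OTU_0028	27	53	81	82	37	277	876	451	1414	165	987	37	60	214	618	23	545	555	903	110	343	37	487	36	16	949	286	207	182	246	137	157	14	66	103	8	203	61	2345	1772
OTU_0029	17	2	285	11	12	23	12	51	32	3	23	38	3	39	6	34	1987	260	218	18	42	22	9	10	16	6	11	92	109	10	3	291	100	3	1472	26	24	10	32	141
OTU_0030	487	392	152	49	82	148	240	24	128	181	41	114	646	4519	1305	1132	355	224	95	395	392	161	63	11	25	223	140	38	37	165	821	184	1922	127	17	140	1124	1839	35	1402
OTU_0031	140	2425	529	4103	651	50	212	4759	724	65	150	238	20	98	1251	489	119	276	242	59	1152	36	13	70	303	241	31	82	902	33	701	6	116	308	117	84	267	54	178	85
OTU_0032	107	515	180	146	146	141	23	80	91	539	2724	120	538	854	1493	44	24	355	49	90	1000	117	2046	1818	62	302	58	146	604	94	69	4220	86	278	1384	91	149	86	107	82
OTU_0033	1285	66	1062	137	74	59	113	184	111	363	67	72	81	61	44	131	175	99	1012	60	2286	215	25	401	20	4469	161	192	233	1788	234	1052	231	985	685	1019	26	2226	128	19
OTU_0034	164	1525	15	137	35	90	28	77	136	991	1928	978	846	124	520	1098	185	420	256	423	382	549	118	443	1167	142	12947	144	1082	1073	1922	18	37	62	38	258	295	295	190	1449
OTU_0035	3213	188	84	270	254	227	219	471	208	199	178	27	725	231	1311	1868	497	53	3007	546	107	55	85	180	378	121	860	70	1728	1980	127	54	997	2484	10378	40	942	3780	332	514
OTU_0036	72	72	7	187	49	50	20	39	34	5	24	31	16	7	35	94	258	123	41	14	29	5	202	1492	124	56	199	287	1104	83	36	16	113	63	158	15	8	82	277	1105
OTU_0037	8	73	66	24	127	18	183	46	40	12	112	54	182	9	3	447	12	35	19	79	15	41	96	12	92	831	281	57	40	36	100	240	353	6	59	807	4	128	180	164
OTU_0038	15	47	15	32	42	13	42	21	27	47	160	18	214	90	32	6	65	262	32	22	142	12	209	15	53	15	33	206	145	283	58	25	9	23	40	11	76	84	50	51
OTU_0039	12	1399	505	1040	152	340	2753	497	464	315	133	225	159	141	49	291	120	26	1359	115	424	1305	149	305	216	69	28	84	29	81	70	108	203	155	243	54	347	54	582	140
OTU_0040	2495	1103	614	983	847	1930	215	391	69	1450	1503	147	166	284	220	380	2036	1595	205	526	492	1546	2552	2443	508	306	1202	12930	1985	1463	717	289	1134	459	1136	213	7597	1097	2362	1069
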