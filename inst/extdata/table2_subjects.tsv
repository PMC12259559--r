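sample_id	gender	age	diagnosis	outcome	group	stage	NONO	FCAR	CKAP4	PLEKHO1	BMP6	RNF4
P01	Male	70	SEPSIS	Partial recovery + discharged	sepsis	sepsis	19.22617679	200.8535291	711.6381286	0.858565436	3.580100284	348.4964138
P02	Female	69	SEPSIS + liver abscess	Recovery	sepsis	sepsis	21.93252488	203.6573398	852.1715043	1.664397469	3.91768119	427.5650147
P03	Male	78	SEPTIC SHOCK + MODS	Improvement	sepsis	septic_shock	5.876674533	40.9275386	96.00249531	0.40332088	0.757858283	118.6032719
P04	Female	42	SEPTIC SHOCK + staphylococcus	Partial recovery + discharged	sepsis	septic_shock	34.65520146	139.5849898	218.2745323	2.063366359	6.797479993	435.0387196
P05	Male	76	SEPSIS + gastric track infection	Recovery	sepsis	sepsis	7.185058983	72.50456866	165.995463	0.664342907	1.536875181	251.6020732
P06	Male	52	SEPSIS + gastric track infection	Recovery	sepsis	sepsis	26.81558831	205.0738887	544.9575334	0.299369676	5.296355642	459.8437749
P07	Male	97	SEPTIC SHOCK + MODS	Death	sepsis	septic_shock	132.055447	4344.576989	5693.105028	7.464263932	21.93252488	3269.830191
P08	Female	58	SEPTIC SHOCK + urinary tract infection	Recovery	sepsis	septic_shock	101.1252879	1991.997332	2926.579998	0.14309052	15.18947394	1494.036833
P09	Female	58	SEPSIS + acute pancreatitis + MODS + pneumonia + ARDS	Improvement	sepsis	sepsis	18.25221945	222.0899039	455.0874528	0.594603558	1.918528239	207.2172074
P10	Female	71	SEPSIS	Recovery	sepsis	sepsis	78.24897777	3125.77886	1601.269029	0.873572896	6.56593287	1034.702281
P11	Female	59	SEPTIC SHOCK	Improvement	sepsis	septic_shock	38.45235358	704.2774109	2443.951602	3.986161051	9.9176616	2142.381957
P12	Female	57	SEPSIS	Improvement	sepsis	sepsis	23.02293728	926.0844826	932.5259096	1.765405993	4.438277888	438.0646531
P13	Female	57	SEPSIS	Refused further treatment + discharged	sepsis	sepsis	32.55935015	456.6674019	861.0779292	1.366040257	1.337927555	376.1071701
P14	Female	89	SEPSIS + gastrointestinal perforation + intra-abdominal infections + pneumonia	Recovery	sepsis	sepsis	13.73704698	78.24897777	176.0693527	0.664342907	2.084931522	109.8963759
P15	Male	43	SEPSIS + gallbladder perforation	Recovery	sepsis	sepsis	2.353813474	2528762.297	82.71058116	0.556710809	0.526680518	23.10286713
P16	Female	70	SEPTIC SHOCK + urinary tract infection	Improvement	sepsis	septic_shock	3.655325801	20.32241572	48.84029469	0.216134308	0.469761375	45.72781247
P17	Male	43	SEPSIS	Improvement	sepsis	sepsis	23.50669813	86.52229331	639.145241	1.938579634	2.099433367	240.5178238
P18	Female	56	SEPTIC SHOCK	Recovery	sepsis	septic_shock	20.32241572	20.96629446	1789.077291	0.539614118	2.128740365	455.0874528
P19	Male	78	Severe pneumonia + COVID	Refused further treatment + discharged	sepsis	sepsis	107.6347412	2012.816586	4938.988862	0.986232704	34.2967508	1398.825223
P20	Male	78	SEPSIS + acute liver failure	Improvement	sepsis	sepsis	44.47738303	447.2693227	1443.144453	0.346277367	11.47164198	826.0011614
P21	Female	83	SEPTIC SHOCK	Recovery	sepsis	septic_shock	6.844760205	102.1821935	272.4787667	0.079384436	1.735077374	142.0248924
P22	Male	85	SEPSIS + gastric bleeding	Death	sepsis	sepsis	222.8609442	7281.399244	6338.826214	2.196185628	19.8353232	2702.352201
P23	Male	74	SEPSIS + severe pneumonia	Improvement	sepsis	sepsis	10.92832205	182.278425	389.3705608	1.681792831	2.070529848	152.7469751
P24	Female	60	SEPSIS + anemia	Improvement	sepsis	sepsis	28.05138308	922.8804737	1413.44497	0.609205132	5.314743256	602.5762495
P25	Female	74	SEPSIS + severe pneumonia	Improvement	sepsis	sepsis	136.2393834	2610.300165	9184.592511	4.331900182	37.27147477	4299.639536
P26	Female	77	Severe fever with thrombocytopenia syndrome bunyavirus	Refused further treatment + discharged	sepsis	sepsis	197.4029857	10960.30253	17991.15266	1.705269784	210.8393004	30152.70894
P27	Male	21	SEPTIC SHOCK	Improvement	sepsis	septic_shock	38.58585049	436.5490646	999.456523	0.024433426	8.456144324	482.7056824
P28	Female	49	SEPTIC SHOCK	Improvement	sepsis	septic_shock	47.17661495	1488.867858	2083.798409	2.173469725	5.917550037	903.8878682
P29	Male	74	SEPSIS + severe pneumonia	Improvement	sepsis	sepsis	84.15633665	1239.033947	2460.950629	1.404444876	15.24220797	1305.150082
P30	Female	82	SEPSIS + acute pulmonary edema	Improvement	sepsis	sepsis	504.9511447	4672.56818	8659.091788	0.43077308	48.00124766	4138.809125
P31	Female	73	SEPTIC SHOCK	Improvement	sepsis	septic_shock	28.64080227	266.8712348	685.0189081	0.270743761	7.438439541	403.101684
P32	Female	68	SEPSIS + MODS	Death	sepsis	sepsis	285.0359343	6295.040743	9981.21688	0.311002913	60.54768939	4011.705539
C01	Female	52	Healthy control	NA	healthy	NA	0.444421341	0.755236293	1.140763716	0.323088208	0.359733395	1.105730653
C02	Male	59	Healthy control	NA	healthy	NA	0.697371833	0.526680518	2.531513188	0.47963206	0.170755032	1.536875181
C03	Male	56	Healthy control	NA	healthy	NA	1.01395948	0.029769937	4.377174805	0.888842681	0.24400794	1.613283518
C04	Male	55	Healthy control	NA	healthy	NA	0.615572207	2.203810232	5.296355642	1.117287138	0.519429552	4.531535541
C05	Female	58	Healthy control	NA	healthy	NA	1.301341855	0.765778999	6.844760205	0.803850991	0.484644908	1.500038989
C06	Female	55	Healthy control	NA	healthy	NA	1.853176124	3.363585661	24.00062383	1.494849249	1.32408891	6.190259974
C07	Female	61	Healthy control	NA	healthy	NA	2.703821666	5.333194708	6.498019171	1.226884977	1.771535038	2.289448321
C08	Male	54	Healthy control	NA	healthy	NA	8.0556444	10.41073484	15.03236399	0.942784536	1.409320755	10.51954208
C09	Female	58	Healthy control	NA	healthy	NA	50.91433496	319.5726205	290.0182746	1.542210825	2.419988178	197.4029857
C10	Female	55	Healthy control	NA	healthy	NA	35.50622311	363.2955792	344.8917957	0.117034031	4.823231311	188.7064598
C11	Female	55	Healthy control	NA	healthy	NA	48.33512274	223.6346614	692.1783465	0.22298213	4.141059695	120.6764206
C12	Female	50	Healthy control	NA	healthy	NA	57.08342524	256	238.8564458	2.74156561	3.434261746	19.09337189
C13	Female	50	Healthy control	NA	healthy	NA	26.90868529	143.509258	481.0356476	3.171136546	1.952063522	83.28587875
C14	Male	56	Healthy control	NA	healthy	NA	42.37084513	116.5657387	374.8059382	0.030395467	3.305801273	109.8963759
C15	Male	60	Healthy control	NA	healthy	NA	10.81528666	21.85664411	182.9112499	0.852634892	0.373712312	30.06472797
C16	Male	59	Healthy control	NA	healthy	NA	114.5632091	367.0925435	1584.706553	0.033377044	7.387058486	30.2738447
C17	Male	54	Healthy control	NA	healthy	NA	8.876555777	41.78751319	226.7564849	1.152686347	0.347479555	58.68825877
C18	Female	65	Healthy control	NA	healthy	NA	5.098242509	2.496661098	3.237768866	4.9588308	2.070529848	68.83164099
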