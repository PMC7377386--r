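gender	age_band	sepsis_events	prior_infection_30d	same_date_ab	p_infection	p_sepsis	p_inf_given_sepsis	p_ab_given_infection	p_sepsis_no_ab	p_sepsis_ab	nnt	nnt_lower	nnt_upper
male	0-4	224	51	11	0.08	0.000014	0.23	0.43	0.000054	0.000020	29773	18458	71091
male	5-14	303	48	6	0.04	0.000006	0.16	0.48	0.000047	0.000008	25606	17962	40817
male	15-24	360	59	21	0.02	0.000008	0.17	0.58	0.000101	0.000041	16921	10285	39551
male	25-34	449	78	18	0.02	0.000009	0.17	0.60	0.000193	0.000039	6517	4779	9522
male	35-44	791	117	24	0.02	0.000013	0.15	0.62	0.000239	0.000039	5035	3980	6610
male	45-54	1342	241	47	0.02	0.000022	0.18	0.62	0.000472	0.000071	2497	2121	2999
male	55-64	2466	472	102	0.02	0.000048	0.19	0.63	0.000825	0.000135	1449	1282	1652
male	65-74	3933	724	155	0.03	0.000105	0.18	0.64	0.001305	0.000202	907	823	1007
male	75-84	4752	1089	256	0.04	0.000219	0.23	0.63	0.002700	0.000478	450	413	492
male	85+	2738	713	158	0.05	0.000416	0.26	0.61	0.004647	0.000833	262	236	293
female	0-4	204	55	12	0.08	0.000014	0.27	0.43	0.000060	0.000023	27014	16739	65709
female	5-14	238	32	9	0.04	0.000005	0.14	0.51	0.000025	0.000010	65522	35239	240067
female	15-24	500	76	24	0.04	0.000012	0.15	0.61	0.000080	0.000024	18120	12472	30241
female	25-34	806	110	38	0.04	0.000016	0.14	0.63	0.000105	0.000033	13926	10044	21273
female	35-44	1095	175	41	0.04	0.000018	0.16	0.66	0.000184	0.000030	6513	5349	8194
female	45-54	1631	267	72	0.03	0.000028	0.16	0.66	0.000278	0.000054	4463	3756	5421
female	55-64	2443	445	119	0.04	0.000048	0.18	0.67	0.000490	0.000088	2486	2179	2876
female	65-74	3215	646	180	0.04	0.000080	0.20	0.67	0.000793	0.000151	1557	1388	1758
female	75-84	3982	890	204	0.05	0.000138	0.22	0.66	0.001525	0.000231	773	705	847
female	85+	3772	984	222	0.05	0.000271	0.26	0.64	0.003110	0.000509	385	352	421
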