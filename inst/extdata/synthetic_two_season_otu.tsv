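#OTU_ID	wet_site01	wet_site02	wet_site03	wet_site04	wet_site05	wet_site06	wet_site07	wet_site08	wet_site09	wet_site10	dry_site01	dry_site02	dry_site03	dry_site04	dry_site05	dry_site06	dry_site07	dry_site08	dry_site09	dry_site10
otu00001	0	0	2	0	0	0	0	3	1	2	0	0	3	1	2	2	4	0	0	0
otu00002	11	7	21	11	27	31	14	17	15	14	29	12	6	10	5	26	18	15	6	16
otu00003	0	0	0	0	0	0	0	1	0	0	0	16	0	14	0	0	0	0	5	1
otu00004	9	8	4	11	6	6	1	19	1	6	2	1	3	11	0	0	12	9	12	7
otu00005	9	11	4	3	11	8	2	5	10	18	1	13	4	0	6	7	6	1	2	9
otu00006	32	40	36	29	40	35	33	17	37	42	32	62	45	55	43	25	70	58	21	44
otu00007	9	21	13	15	2	4	17	14	18	10	8	16	7	24	8	20	14	3	12	33
otu00008	2	6	3	8	1	3	1	5	6	2	0	0	9	0	16	0	1	0	6	0
otu00009	36	27	31	47	12	31	37	33	43	32	14	5	11	37	72	11	14	39	12	27
otu00010	3	1	11	3	0	4	0	0	1	0	1	0	5	0	3	7	0	0	0	17
otu00011	14	14	28	14	15	5	15	13	18	8	12	10	7	4	24	4	8	13	4	5
otu00012	0	2	0	0	2	0	0	0	9	0	0	0	0	0	0	0	1	0	0	0
otu00013	74	70	72	74	65	63	43	73	57	75	74	83	67	46	70	107	42	48	119	30
otu00014	0	1	0	0	0	0	0	0	4	0	0	0	0	0	0	0	0	0	0	0
otu00015	0	0	2	0	0	0	3	4	7	5	1	5	2	0	0	0	7	0	2	0
otu00016	0	1	10	7	4	6	6	0	0	6	9	0	12	21	1	0	8	5	1	1
otu00017	1	0	0	0	0	0	1	0	0	0	0	0	0	0	0	0	0	0	0	0
otu00018	2	5	7	1	5	0	1	7	4	0	2	2	8	18	0	7	1	0	1	2
otu00019	2	0	0	0	0	0	0	0	0	3	0	4	1	1	0	0	5	0	0	0
otu00021	7	0	0	3	0	11	0	2	1	3	1	3	3	7	0	0	0	5	14	0
otu00022	6	20	14	18	9	3	12	12	15	25	14	10	31	14	11	9	7	8	23	10
otu00023	4	1	0	1	21	4	5	3	0	0	1	0	2	5	0	0	1	1	0	0
otu00024	0	0	0	0	0	2	0	0	0	0	0	0	0	0	0	0	0	0	0	0
otu00025	27	9	14	51	4	11	6	15	27	37	9	3	7	27	7	10	36	10	10	27
otu00026	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	2
otu00027	13	24	7	5	10	13	20	10	5	9	1	10	4	1	14	8	24	12	8	11
otu00028	0	1	0	6	3	3	0	8	1	3	4	9	13	0	0	2	2	0	1	0
otu00029	12	13	5	8	10	6	28	16	8	6	11	16	15	18	13	26	18	8	3	12
otu00030	14	12	17	4	13	20	8	10	9	10	18	29	2	1	14	13	10	10	9	16
otu00031	28	27	18	24	25	25	18	25	29	9	51	6	13	29	20	29	12	16	17	15
otu00032	14	27	4	2	5	4	3	8	4	1	2	22	11	3	1	23	0	10	3	0
otu00033	40	39	24	39	22	18	13	23	21	15	31	30	31	15	14	35	30	0	39	22
otu00034	0	0	0	0	0	0	1	0	0	0	0	0	0	0	0	0	0	0	0	0
otu00035	29	41	29	34	27	52	34	35	54	26	22	39	19	54	46	44	53	34	33	39
otu00036	0	2	0	0	0	0	0	8	0	2	1	0	0	0	7	0	0	7	0	0
otu00037	6	4	19	3	2	18	8	6	5	11	4	0	3	10	0	2	2	3	2	4
otu00038	13	38	35	31	21	20	30	11	25	20	20	6	29	39	12	34	24	13	21	30
otu00040	4	7	5	10	18	32	23	25	7	13	6	35	1	6	10	4	2	4	11	19
otu00041	20	9	9	6	8	20	17	25	11	20	30	7	5	22	19	4	27	4	4	20
otu00042	19	23	43	29	31	23	7	15	14	23	12	4	49	6	13	33	12	21	10	7
otu00044	0	1	2	5	4	1	2	1	1	1	0	2	0	0	1	0	13	0	1	0
otu00045	0	0	0	0	4	0	0	0	0	0	0	0	0	4	0	0	0	0	0	0
otu00046	18	6	3	13	7	5	3	3	8	1	2	8	3	2	6	36	14	0	0	23
otu00047	8	22	8	8	7	5	23	5	11	9	5	1	7	12	5	8	5	3	4	14
otu00048	0	1	5	1	1	0	0	1	3	0	2	0	0	0	5	0	0	0	0	0
otu00049	2	0	3	0	1	0	0	5	1	0	2	1	0	1	1	0	0	0	3	0
otu00050	0	0	0	0	0	0	1	0	1	0	0	0	0	2	0	0	0	0	0	0
otu00051	0	1	0	0	0	0	0	0	0	0	0	5	0	0	0	0	0	0	0	0
otu00052	1	10	0	4	0	3	1	0	0	1	0	0	5	12	10	1	0	5	10	3
otu00053	11	11	21	26	13	25	2	6	13	10	17	15	6	13	14	8	31	7	20	7
otu00055	13	22	25	13	18	12	29	18	17	30	4	55	3	8	3	7	7	24	53	78
otu00056	0	2	0	2	1	0	0	0	0	0	0	0	0	0	0	0	3	0	0	0
otu00057	1	6	8	4	7	9	15	1	16	0	0	14	5	0	6	6	0	2	20	14
otu00058	44	19	36	36	60	32	25	38	26	34	53	20	19	17	30	8	38	12	27	46
otu00059	45	29	26	40	56	73	67	49	34	60	70	23	88	64	16	24	67	127	55	47
otu00060	0	12	1	1	2	8	0	0	1	0	1	0	0	0	0	6	1	0	0	0
otu00061	4	2	2	7	1	9	3	3	10	0	0	0	0	0	0	0	0	0	1	3
otu00062	0	0	0	0	0	0	0	0	1	0	0	0	0	0	0	0	0	0	0	1
otu00063	7	0	0	1	0	0	2	0	0	6	0	0	0	0	0	0	0	0	0	0
otu00064	7	6	18	6	7	17	4	2	28	15	4	22	11	6	1	11	0	0	5	0
otu00065	11	6	6	6	9	13	6	12	16	16	18	8	20	16	11	7	19	6	10	21
otu00066	12	15	2	3	18	6	2	6	5	25	19	0	1	2	3	3	7	23	0	4
otu00067	0	1	3	5	3	0	0	1	0	0	0	0	2	0	0	0	0	1	2	17
otu00068	2	2	3	8	2	3	10	8	4	5	3	8	0	1	5	1	1	1	4	5
otu00069	0	4	2	3	1	4	1	2	1	4	5	0	0	0	0	2	6	0	1	0
otu00070	1	0	6	3	2	16	2	1	5	5	1	7	0	11	1	11	3	13	1	3
otu00071	75	61	77	81	127	110	139	92	92	74	139	52	53	24	115	117	56	119	96	42
otu00072	82	81	103	78	57	81	151	100	102	83	99	123	159	58	87	78	51	81	99	118
otu00073	39	36	28	28	55	31	38	35	31	22	20	49	21	27	9	49	46	20	84	15
otu00074	7	3	0	2	0	3	0	0	7	2	2	0	3	1	3	27	1	4	0	6
otu00076	1	9	0	0	0	0	0	1	0	0	23	0	0	0	0	1	0	0	0	0
otu00077	15	9	4	6	3	9	13	1	6	5	19	3	2	10	7	0	10	2	4	1
otu00078	1	0	0	3	0	1	1	0	0	0	0	8	0	1	0	0	4	0	0	0
otu00079	3	3	4	5	5	5	8	3	4	6	0	7	14	14	1	0	15	5	6	12
otu00080	0	0	1	10	16	5	7	4	0	1	0	0	3	2	2	2	3	0	6	1
otu00081	151	182	146	175	140	129	143	162	124	156	107	137	153	158	124	157	238	147	218	179
otu00082	39	28	31	46	59	44	30	28	40	50	13	28	91	56	33	40	28	24	39	21
otu00083	0	1	0	1	0	0	0	3	2	5	0	1	0	2	0	0	12	7	0	1
otu00084	0	0	0	0	3	0	3	6	3	3	0	0	0	0	0	0	0	0	0	0
otu00085	0	0	1	0	0	0	0	0	0	0	0	0	0	0	9	0	0	4	0	0
otu00086	17	6	12	18	10	8	7	17	11	0	13	1	22	6	0	4	10	5	0	6
otu00087	4	4	5	2	1	12	1	1	1	1	2	0	6	1	5	13	0	5	0	1
otu00088	74	41	40	47	72	45	72	60	47	60	65	32	99	57	25	83	74	87	39	29
otu00089	23	8	16	3	6	10	14	12	18	19	42	12	15	9	5	41	9	44	8	11
otu00090	84	89	69	79	64	69	70	113	72	70	77	94	79	86	55	86	89	76	57	103
otu00091	46	38	51	60	35	42	41	34	50	53	37	79	46	46	53	30	65	33	67	54
otu00092	4	1	2	3	9	0	4	0	7	1	9	0	1	2	5	0	1	2	0	0
otu00093	0	1	2	0	2	0	3	2	0	1	0	0	0	0	0	1	0	0	0	1
otu00094	2	0	0	0	0	0	0	0	0	1	0	0	0	0	0	0	0	5	0	0
otu00095	10	4	3	4	16	12	6	11	11	2	4	5	1	3	28	10	6	28	4	0
otu00096	0	0	5	1	0	0	0	0	0	0	0	0	0	0	0	0	0	0	3	0
otu00097	2	1	0	4	0	0	0	1	1	2	5	3	1	0	1	0	0	1	1	0
otu00098	49	74	74	72	53	50	66	49	53	66	68	34	26	99	44	58	58	103	24	32
otu00099	7	1	8	1	14	11	6	13	9	6	4	6	24	10	0	14	1	5	5	2
otu00100	0	3	0	0	0	1	5	0	0	0	0	0	0	0	0	0	0	0	0	0
otu00101	4	2	5	4	5	0	12	3	8	15	17	16	2	0	0	14	3	0	13	0
otu00102	2	2	0	3	1	0	0	2	0	0	0	0	0	0	0	0	0	0	0	0
otu00103	269	284	271	229	254	287	240	260	296	282	215	274	216	380	432	250	208	254	280	282
otu00104	38	38	47	49	54	25	36	37	36	24	75	39	43	28	77	43	20	48	27	50
otu00105	6	17	18	16	12	28	23	10	12	17	10	5	22	5	15	14	25	12	2	34
otu00106	0	7	4	0	1	6	0	1	3	9	0	0	0	0	0	15	1	0	0	0
otu00107	4	6	1	4	1	1	6	1	1	11	4	0	0	2	1	11	11	2	0	4
otu00108	0	0	0	0	0	0	0	0	0	0	0	0	3	0	0	0	0	0	0	0
otu00109	2	9	1	0	5	0	0	0	0	4	0	0	0	0	0	0	6	1	1	0
otu00110	137	127	123	85	122	91	94	112	129	131	166	134	92	136	134	96	133	165	159	107
otu00111	0	1	0	0	0	0	4	0	2	1	0	4	0	0	2	1	0	0	0	4
otu00112	1	1	9	5	0	1	2	4	2	4	0	0	3	0	17	2	2	8	0	3
otu00113	1	2	7	2	1	3	0	16	4	4	2	2	15	0	2	0	0	3	14	4
otu00114	101	87	113	110	106	87	91	104	90	91	75	166	125	53	89	80	75	90	67	116
otu00115	12	7	17	32	21	18	26	22	10	18	30	7	27	40	25	6	27	14	23	18
otu00116	0	0	0	3	0	1	0	1	0	0	0	1	2	0	3	0	0	0	2	0
otu00117	0	1	0	0	0	7	4	3	0	0	0	8	0	0	0	0	1	0	0	0
otu00118	2	1	1	0	0	0	3	0	0	0	0	0	0	0	1	0	0	0	0	3
otu00119	0	0	0	7	3	2	6	0	0	3	0	0	0	0	0	0	2	0	15	6
otu00120	39	35	34	30	24	43	20	46	47	19	29	23	33	14	22	26	23	15	9	22
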