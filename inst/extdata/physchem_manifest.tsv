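index	name	family	accession	stat
1	length	length	NA	global
2	molecular_weight	mass	FASG760101	global
3	aromaticity	aromaticity	NA	global
4	instability_index	instability	DIWV_Guruprasad1990	global
5	gravy	hydrophobicity	KYTJ820101	global
6	isoelectric_point	isoelectric_point	NA	global
7	kytj820101_mean	hydrophobicity	KYTJ820101	mean
8	kytj820101_sd	hydrophobicity	KYTJ820101	sd
9	kytj820101_min	hydrophobicity	KYTJ820101	min
10	kytj820101_max	hydrophobicity	KYTJ820101	max
11	kytj820101_mb1	hydrophobicity	KYTJ820101	mb1
12	kytj820101_mb2	hydrophobicity	KYTJ820101	mb2
13	kytj820101_mb3	hydrophobicity	KYTJ820101	mb3
14	kytj820101_mb4	hydrophobicity	KYTJ820101	mb4
15	kytj820101_mb5	hydrophobicity	KYTJ820101	mb5
16	kytj820101_mb6	hydrophobicity	KYTJ820101	mb6
17	kytj820101_mb7	hydrophobicity	KYTJ820101	mb7
18	kytj820101_mb8	hydrophobicity	KYTJ820101	mb8
19	kytj820101_mb9	hydrophobicity	KYTJ820101	mb9
20	kytj820101_mb10	hydrophobicity	KYTJ820101	mb10
21	kytj820101_mb11	hydrophobicity	KYTJ820101	mb11
22	vinm940101_mean	flexibility	VINM940101	mean
23	vinm940101_sd	flexibility	VINM940101	sd
24	vinm940101_min	flexibility	VINM940101	min
25	vinm940101_max	flexibility	VINM940101	max
26	vinm940101_mb1	flexibility	VINM940101	mb1
27	vinm940101_mb2	flexibility	VINM940101	mb2
28	vinm940101_mb3	flexibility	VINM940101	mb3
29	vinm940101_mb4	flexibility	VINM940101	mb4
30	vinm940101_mb5	flexibility	VINM940101	mb5
31	vinm940101_mb6	flexibility	VINM940101	mb6
32	vinm940101_mb7	flexibility	VINM940101	mb7
33	vinm940101_mb8	flexibility	VINM940101	mb8
34	vinm940101_mb9	flexibility	VINM940101	mb9
35	vinm940101_mb10	flexibility	VINM940101	mb10
36	vinm940101_mb11	flexibility	VINM940101	mb11
37	cham820101_mean	polarizability	CHAM820101	mean
38	cham820101_sd	polarizability	CHAM820101	sd
39	cham820101_min	polarizability	CHAM820101	min
40	cham820101_max	polarizability	CHAM820101	max
41	cham820101_mb1	polarizability	CHAM820101	mb1
42	cham820101_mb2	polarizability	CHAM820101	mb2
43	cham820101_mb3	polarizability	CHAM820101	mb3
44	cham820101_mb4	polarizability	CHAM820101	mb4
45	cham820101_mb5	polarizability	CHAM820101	mb5
46	cham820101_mb6	polarizability	CHAM820101	mb6
47	cham820101_mb7	polarizability	CHAM820101	mb7
48	cham820101_mb8	polarizability	CHAM820101	mb8
49	cham820101_mb9	polarizability	CHAM820101	mb9
50	cham820101_mb10	polarizability	CHAM820101	mb10
51	cham820101_mb11	polarizability	CHAM820101	mb11
52	cham820102_mean	free_energy	CHAM820102	mean
53	cham820102_sd	free_energy	CHAM820102	sd
54	cham820102_min	free_energy	CHAM820102	min
55	cham820102_max	free_energy	CHAM820102	max
56	cham820102_mb1	free_energy	CHAM820102	mb1
57	cham820102_mb2	free_energy	CHAM820102	mb2
58	cham820102_mb3	free_energy	CHAM820102	mb3
59	cham820102_mb4	free_energy	CHAM820102	mb4
60	cham820102_mb5	free_energy	CHAM820102	mb5
61	cham820102_mb6	free_energy	CHAM820102	mb6
62	cham820102_mb7	free_energy	CHAM820102	mb7
63	cham820102_mb8	free_energy	CHAM820102	mb8
64	cham820102_mb9	free_energy	CHAM820102	mb9
65	cham820102_mb10	free_energy	CHAM820102	mb10
66	cham820102_mb11	free_energy	CHAM820102	mb11
67	cham810101_mean	steric	CHAM810101	mean
68	cham810101_sd	steric	CHAM810101	sd
69	cham810101_min	steric	CHAM810101	min
70	cham810101_max	steric	CHAM810101	max
71	cham810101_mb1	steric	CHAM810101	mb1
72	cham810101_mb2	steric	CHAM810101	mb2
73	cham810101_mb3	steric	CHAM810101	mb3
74	cham810101_mb4	steric	CHAM810101	mb4
75	cham810101_mb5	steric	CHAM810101	mb5
76	cham810101_mb6	steric	CHAM810101	mb6
77	cham810101_mb7	steric	CHAM810101	mb7
78	cham810101_mb8	steric	CHAM810101	mb8
79	cham810101_mb9	steric	CHAM810101	mb9
80	cham810101_mb10	steric	CHAM810101	mb10
81	cham810101_mb11	steric	CHAM810101	mb11
82	grar740102_mean	polarity	GRAR740102	mean
83	grar740102_sd	polarity	GRAR740102	sd
84	grar740102_min	polarity	GRAR740102	min
85	grar740102_max	polarity	GRAR740102	max
86	grar740102_mb1	polarity	GRAR740102	mb1
87	grar740102_mb2	polarity	GRAR740102	mb2
88	grar740102_mb3	polarity	GRAR740102	mb3
89	grar740102_mb4	polarity	GRAR740102	mb4
90	grar740102_mb5	polarity	GRAR740102	mb5
91	grar740102_mb6	polarity	GRAR740102	mb6
92	grar740102_mb7	polarity	GRAR740102	mb7
93	grar740102_mb8	polarity	GRAR740102	mb8
94	grar740102_mb9	polarity	GRAR740102	mb9
95	grar740102_mb10	polarity	GRAR740102	mb10
96	grar740102_mb11	polarity	GRAR740102	mb11
97	zimj680104_mean	residue_pI	ZIMJ680104	mean
98	zimj680104_sd	residue_pI	ZIMJ680104	sd
99	zimj680104_min	residue_pI	ZIMJ680104	min
100	zimj680104_max	residue_pI	ZIMJ680104	max
101	zimj680104_mb1	residue_pI	ZIMJ680104	mb1
102	zimj680104_mb2	residue_pI	ZIMJ680104	mb2
103	zimj680104_mb3	residue_pI	ZIMJ680104	mb3
104	zimj680104_mb4	residue_pI	ZIMJ680104	mb4
105	zimj680104_mb5	residue_pI	ZIMJ680104	mb5
106	zimj680104_mb6	residue_pI	ZIMJ680104	mb6
107	zimj680104_mb7	residue_pI	ZIMJ680104	mb7
108	zimj680104_mb8	residue_pI	ZIMJ680104	mb8
109	zimj680104_mb9	residue_pI	ZIMJ680104	mb9
110	zimj680104_mb10	residue_pI	ZIMJ680104	mb10
111	zimj680104_mb11	residue_pI	ZIMJ680104	mb11
112	bigc670101_mean	volume	BIGC670101	mean
113	bigc670101_sd	volume	BIGC670101	sd
114	bigc670101_min	volume	BIGC670101	min
115	bigc670101_max	volume	BIGC670101	max
116	bigc670101_mb1	volume	BIGC670101	mb1
117	bigc670101_mb2	volume	BIGC670101	mb2
118	bigc670101_mb3	volume	BIGC670101	mb3
119	bigc670101_mb4	volume	BIGC670101	mb4
120	bigc670101_mb5	volume	BIGC670101	mb5
121	bigc670101_mb6	volume	BIGC670101	mb6
122	bigc670101_mb7	volume	BIGC670101	mb7
123	bigc670101_mb8	volume	BIGC670101	mb8
124	bigc670101_mb9	volume	BIGC670101	mb9
125	bigc670101_mb10	volume	BIGC670101	mb10
126	bigc670101_mb11	volume	BIGC670101	mb11
127	fasg760101_mean	residue_mass	FASG760101	mean
128	fasg760101_sd	residue_mass	FASG760101	sd
129	fasg760101_min	residue_mass	FASG760101	min
130	fasg760101_max	residue_mass	FASG760101	max
131	fasg760101_mb1	residue_mass	FASG760101	mb1
132	fasg760101_mb2	residue_mass	FASG760101	mb2
133	fasg760101_mb3	residue_mass	FASG760101	mb3
134	fasg760101_mb4	residue_mass	FASG760101	mb4
135	fasg760101_mb5	residue_mass	FASG760101	mb5
136	fasg760101_mb6	residue_mass	FASG760101	mb6
137	fasg760101_mb7	residue_mass	FASG760101	mb7
138	fasg760101_mb8	residue_mass	FASG760101	mb8
139	fasg760101_mb9	residue_mass	FASG760101	mb9
140	fasg760101_mb10	residue_mass	FASG760101	mb10
141	fasg760101_mb11	residue_mass	FASG760101	mb11
142	hopt810101_mean	hydrophilicity	HOPT810101	mean
143	hopt810101_sd	hydrophilicity	HOPT810101	sd
144	hopt810101_min	hydrophilicity	HOPT810101	min
145	hopt810101_max	hydrophilicity	HOPT810101	max
146	hopt810101_mb1	hydrophilicity	HOPT810101	mb1
147	hopt810101_mb2	hydrophilicity	HOPT810101	mb2
148	hopt810101_mb3	hydrophilicity	HOPT810101	mb3
149	hopt810101_mb4	hydrophilicity	HOPT810101	mb4
150	hopt810101_mb5	hydrophilicity	HOPT810101	mb5
151	hopt810101_mb6	hydrophilicity	HOPT810101	mb6
152	hopt810101_mb7	hydrophilicity	HOPT810101	mb7
153	hopt810101_mb8	hydrophilicity	HOPT810101	mb8
154	hopt810101_mb9	hydrophilicity	HOPT810101	mb9
155	hopt810101_mb10	hydrophilicity	HOPT810101	mb10
156	hopt810101_mb11	hydrophilicity	HOPT810101	mb11
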