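index	abbreviation	name	hemisphere	func_class	provenance
1	PreCG	Precental gyrus	L	paralimbic	printed
2	PreCG	Precental gyrus	R	paralimbic	mirrored
3	SFGdor	Superior frontal gyrus, dorsolateral	L	association	inferred
4	SFGdor	Superior frontal gyrus, dorsolateral	R	association	inferred
5	ORBsup	Superior frontal gyrus, orbital part	L	paralimbic	inferred
6	ORBsup	Superior frontal gyrus, orbital part	R	paralimbic	inferred
7	MFG	Middle frontal gyrus	L	association	printed
8	MFG	Middle frontal gyrus	R	association	printed
9	ORBmid	Middle frontal gyrus, orbital part	L	paralimbic	printed
10	ORBmid	Middle frontal gyrus, orbital part	R	paralimbic	mirrored
11	IFGoperc	Inferior frontal gyrus, opercular part	L	association	inferred
12	IFGoperc	Inferior frontal gyrus, opercular part	R	association	inferred
13	IFGtriang	Inferior frontal gyrus, triangular part	L	association	printed
14	IFGtriang	Inferior frontal gyrus, triangular part	R	association	mirrored
15	ORBinf	Inferior frontal gyrus, orbital part	L	paralimbic	inferred
16	ORBinf	Inferior frontal gyrus, orbital part	R	paralimbic	inferred
17	ROL	Rolandic operculum	L	association	inferred
18	ROL	Rolandic operculum	R	association	inferred
19	SMA	Supplementary motor area	L	association	mirrored
20	SMA	Supplementary motor area	R	association	printed
21	OLF	Olfactory cortex	L	paralimbic	printed
22	OLF	Olfactory cortex	R	paralimbic	printed
23	SFGmed	Superior frontal gyrus, medial	L	association	inferred
24	SFGmed	Superior frontal gyrus, medial	R	association	inferred
25	ORBsupmed	Superior frontal gyrus, medial orbital	L	paralimbic	printed
26	ORBsupmed	Superior frontal gyrus, medial orbital	R	paralimbic	mirrored
27	REC	Gyrus rectus	L	association	printed
28	REC	Gyrus rectus	R	association	printed
29	INS	Insula	L	paralimbic	printed
30	INS	Insula	R	paralimbic	printed
31	ACG	Anterior cingulate and paracingulate gyri	L	paralimbic	inferred
32	ACG	Anterior cingulate and paracingulate gyri	R	paralimbic	inferred
33	DCG	Median cingulate and paracingulate gyri	L	paralimbic	inferred
34	DCG	Median cingulate and paracingulate gyri	R	paralimbic	inferred
35	PCG	Posterior cingulate gyrus	L	paralimbic	inferred
36	PCG	Posterior cingulate gyrus	R	paralimbic	inferred
37	HIP	Hippocampus	L	paralimbic	mirrored
38	HIP	Hippocampus	R	paralimbic	printed
39	PHG	Parahippocampal gyrus	L	paralimbic	printed
40	PHG	Parahippocampal gyrus	R	paralimbic	printed
41	AMYG	Amygdala	L	paralimbic	inferred
42	AMYG	Amygdala	R	paralimbic	inferred
43	CAL	Calcarine fissure and surrounding cortex	L	primary	inferred
44	CAL	Calcarine fissure and surrounding cortex	R	primary	inferred
45	CUN	Cuneus	L	association	mirrored
46	CUN	Cuneus	R	association	printed
47	LING	Lingual gyrus	L	association	inferred
48	LING	Lingual gyrus	R	association	inferred
49	SOG	Superior occipital gyrus	L	association	printed
50	SOG	Superior occipital gyrus	R	association	mirrored
51	MOG	Middle occipital gyrus	L	association	printed
52	MOG	Middle occipital gyrus	R	association	mirrored
53	IOG	Inferior occipital gyrus	L	association	inferred
54	IOG	Inferior occipital gyrus	R	association	inferred
55	FFG	Fusiform gyrus	L	association	mirrored
56	FFG	Fusiform gyrus	R	association	printed
57	PoCG	Postcentral gyrus	L	paralimbic	printed
58	PoCG	Postcentral gyrus	R	paralimbic	mirrored
59	SPG	Superior parietal gyrus	L	association	printed
60	SPG	Superior parietal gyrus	R	association	printed
61	IPL	Inferior parietal, but supramarginal and angular gyri	L	association	inferred
62	IPL	Inferior parietal, but supramarginal and angular gyri	R	association	inferred
63	SMG	Supramarginal gyrus	L	association	printed
64	SMG	Supramarginal gyrus	R	association	mirrored
65	ANG	Angular gyrus	L	association	printed
66	ANG	Angular gyrus	R	association	printed
67	PCUN	Precuneus	L	association	printed
68	PCUN	Precuneus	R	association	printed
69	PCL	Paracentral lobule	L	association	mirrored
70	PCL	Paracentral lobule	R	association	printed
71	CAU	Caudate nucleus	L	subcortical	mirrored
72	CAU	Caudate nucleus	R	subcortical	printed
73	PUT	Lenticular nucleus, putamen	L	subcortical	inferred
74	PUT	Lenticular nucleus, putamen	R	subcortical	inferred
75	PAL	Lenticular nucleus, pallidum	L	subcortical	inferred
76	PAL	Lenticular nucleus, pallidum	R	subcortical	inferred
77	THA	Thalamus	L	subcortical	mirrored
78	THA	Thalamus	R	subcortical	printed
79	HES	Heschl gyrus	L	paralimbic	printed
80	HES	Heschl gyrus	R	paralimbic	printed
81	STG	Superior temporal gyrus	L	association	mirrored
82	STG	Superior temporal gyrus	R	association	printed
83	TPOsup	Temporal pole: superior temporal gyrus	L	paralimbic	printed
84	TPOsup	Temporal pole: superior temporal gyrus	R	paralimbic	mirrored
85	MTG	Middle temporal gyrus	L	association	inferred
86	MTG	Middle temporal gyrus	R	association	inferred
87	TPOmid	Temporal pole: middle temporal gyrus	L	paralimbic	inferred
88	TPOmid	Temporal pole: middle temporal gyrus	R	paralimbic	inferred
89	ITG	Inferior temporal gyrus	L	association	inferred
90	ITG	Inferior temporal gyrus	R	association	inferred
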