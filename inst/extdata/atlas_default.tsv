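region_id	name	hemisphere	is_seed
1	Precentral_L	L	1
2	Precentral_R	R	1
3	Frontal_Sup_L	L	0
4	Frontal_Sup_R	R	0
5	Frontal_Sup_Orb_L	L	0
6	Frontal_Sup_Orb_R	R	0
7	Frontal_Mid_L	L	0
8	Frontal_Mid_R	R	0
9	Frontal_Mid_Orb_L	L	0
10	Frontal_Mid_Orb_R	R	0
11	Frontal_Inf_Oper_L	L	1
12	Frontal_Inf_Oper_R	R	1
13	Frontal_Inf_Tri_L	L	1
14	Frontal_Inf_Tri_R	R	1
15	Frontal_Inf_Orb_L	L	1
16	Frontal_Inf_Orb_R	R	1
17	Rolandic_Oper_L	L	0
18	Rolandic_Oper_R	R	0
19	Supp_Motor_Area_L	L	0
20	Supp_Motor_Area_R	R	0
21	Olfactory_L	L	0
22	Olfactory_R	R	0
23	Frontal_Sup_Medial_L	L	0
24	Frontal_Sup_Medial_R	R	0
25	Frontal_Med_Orb_L	L	0
26	Frontal_Med_Orb_R	R	0
27	Rectus_L	L	0
28	Rectus_R	R	0
29	Insula_L	L	0
30	Insula_R	R	0
31	Cingulum_Ant_L	L	0
32	Cingulum_Ant_R	R	0
33	Cingulum_Mid_L	L	0
34	Cingulum_Mid_R	R	0
35	Cingulum_Post_L	L	0
36	Cingulum_Post_R	R	0
37	Hippocampus_L	L	0
38	Hippocampus_R	R	0
39	ParaHippocampal_L	L	0
40	ParaHippocampal_R	R	0
41	Amygdala_L	L	0
42	Amygdala_R	R	0
43	Calcarine_L	L	0
44	Calcarine_R	R	0
45	Cuneus_L	L	0
46	Cuneus_R	R	0
47	Lingual_L	L	0
48	Lingual_R	R	0
49	Occipital_Sup_L	L	0
50	Occipital_Sup_R	R	0
51	Occipital_Mid_L	L	0
52	Occipital_Mid_R	R	0
53	Occipital_Inf_L	L	0
54	Occipital_Inf_R	R	0
55	Fusiform_L	L	1
56	Fusiform_R	R	1
57	Postcentral_L	L	0
58	Postcentral_R	R	0
59	Parietal_Sup_L	L	0
60	Parietal_Sup_R	R	0
61	Parietal_Inf_L	L	1
62	Parietal_Inf_R	R	1
63	SupraMarginal_L	L	1
64	SupraMarginal_R	R	1
65	Angular_L	L	1
66	Angular_R	R	1
67	Precuneus_L	L	0
68	Precuneus_R	R	0
69	Paracentral_Lobule_L	L	0
70	Paracentral_Lobule_R	R	0
71	Caudate_L	L	0
72	Caudate_R	R	0
73	Putamen_L	L	0
74	Putamen_R	R	0
75	Pallidum_L	L	0
76	Pallidum_R	R	0
77	Thalamus_L	L	0
78	Thalamus_R	R	0
79	Heschl_L	L	1
80	Heschl_R	R	1
81	Temporal_Sup_L	L	0
82	Temporal_Sup_R	R	0
83	Temporal_Pole_Sup_L	L	0
84	Temporal_Pole_Sup_R	R	0
85	Temporal_Mid_L	L	0
86	Temporal_Mid_R	R	0
87	Temporal_Pole_Mid_L	L	0
88	Temporal_Pole_Mid_R	R	0
89	Temporal_Inf_L	L	1
90	Temporal_Inf_R	R	1
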