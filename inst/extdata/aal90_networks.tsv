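node	name	network
1	Precentral_L	Somatomotor
2	Precentral_R	Somatomotor
3	Frontal_Sup_L	Frontoparietal
4	Frontal_Sup_R	Frontoparietal
5	Frontal_Sup_Orb_L	Limbic
6	Frontal_Sup_Orb_R	Limbic
7	Frontal_Mid_L	Frontoparietal
8	Frontal_Mid_R	Frontoparietal
9	Frontal_Mid_Orb_L	Limbic
10	Frontal_Mid_Orb_R	Limbic
11	Frontal_Inf_Oper_L	Ventral Attention
12	Frontal_Inf_Oper_R	Ventral Attention
13	Frontal_Inf_Tri_L	Frontoparietal
14	Frontal_Inf_Tri_R	Frontoparietal
15	Frontal_Inf_Orb_L	Limbic
16	Frontal_Inf_Orb_R	Limbic
17	Rolandic_Oper_L	Somatomotor
18	Rolandic_Oper_R	Somatomotor
19	Supp_Motor_Area_L	Somatomotor
20	Supp_Motor_Area_R	Somatomotor
21	Olfactory_L	Limbic
22	Olfactory_R	Limbic
23	Frontal_Sup_Medial_L	Default Mode
24	Frontal_Sup_Medial_R	Default Mode
25	Frontal_Med_Orb_L	Default Mode
26	Frontal_Med_Orb_R	Default Mode
27	Rectus_L	Limbic
28	Rectus_R	Limbic
29	Insula_L	Ventral Attention
30	Insula_R	Ventral Attention
31	Cingulum_Ant_L	Default Mode
32	Cingulum_Ant_R	Default Mode
33	Cingulum_Mid_L	Ventral Attention
34	Cingulum_Mid_R	Ventral Attention
35	Cingulum_Post_L	Default Mode
36	Cingulum_Post_R	Default Mode
37	Hippocampus_L	Subcortical
38	Hippocampus_R	Subcortical
39	ParaHippocampal_L	Limbic
40	ParaHippocampal_R	Limbic
41	Amygdala_L	Subcortical
42	Amygdala_R	Subcortical
43	Calcarine_L	Visual
44	Calcarine_R	Visual
45	Cuneus_L	Visual
46	Cuneus_R	Visual
47	Lingual_L	Visual
48	Lingual_R	Visual
49	Occipital_Sup_L	Visual
50	Occipital_Sup_R	Visual
51	Occipital_Mid_L	Visual
52	Occipital_Mid_R	Visual
53	Occipital_Inf_L	Visual
54	Occipital_Inf_R	Visual
55	Fusiform_L	Visual
56	Fusiform_R	Visual
57	Postcentral_L	Somatomotor
58	Postcentral_R	Somatomotor
59	Parietal_Sup_L	Dorsal Attention
60	Parietal_Sup_R	Dorsal Attention
61	Parietal_Inf_L	Frontoparietal
62	Parietal_Inf_R	Frontoparietal
63	SupraMarginal_L	Ventral Attention
64	SupraMarginal_R	Ventral Attention
65	Angular_L	Default Mode
66	Angular_R	Default Mode
67	Precuneus_L	Default Mode
68	Precuneus_R	Default Mode
69	Paracentral_Lobule_L	Somatomotor
70	Paracentral_Lobule_R	Somatomotor
71	Caudate_L	Subcortical
72	Caudate_R	Subcortical
73	Putamen_L	Subcortical
74	Putamen_R	Subcortical
75	Pallidum_L	Subcortical
76	Pallidum_R	Subcortical
77	Thalamus_L	Subcortical
78	Thalamus_R	Subcortical
79	Heschl_L	Somatomotor
80	Heschl_R	Somatomotor
81	Temporal_Sup_L	Somatomotor
82	Temporal_Sup_R	Somatomotor
83	Temporal_Pole_Sup_L	Limbic
84	Temporal_Pole_Sup_R	Limbic
85	Temporal_Mid_L	Default Mode
86	Temporal_Mid_R	Default Mode
87	Temporal_Pole_Mid_L	Limbic
88	Temporal_Pole_Mid_R	Limbic
89	Temporal_Inf_L	Dorsal Attention
90	Temporal_Inf_R	Dorsal Attention
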