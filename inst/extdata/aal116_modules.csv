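region_index,region_label,module,hemisphere
1,Precentral_L,SMN,L
2,Precentral_R,SMN,R
3,Frontal_Sup_L,FPN,L
4,Frontal_Sup_R,FPN,R
5,Frontal_Sup_Orb_L,FPN,L
6,Frontal_Sup_Orb_R,FPN,R
7,Frontal_Mid_L,FPN,L
8,Frontal_Mid_R,FPN,R
9,Frontal_Mid_Orb_L,FPN,L
10,Frontal_Mid_Orb_R,FPN,R
11,Frontal_Inf_Oper_L,FPN,L
12,Frontal_Inf_Oper_R,FPN,R
13,Frontal_Inf_Tri_L,FPN,L
14,Frontal_Inf_Tri_R,FPN,R
15,Frontal_Inf_Orb_L,FPN,L
16,Frontal_Inf_Orb_R,FPN,R
17,Rolandic_Oper_L,SMN,L
18,Rolandic_Oper_R,SMN,R
19,Supp_Motor_Area_L,SMN,L
20,Supp_Motor_Area_R,SMN,R
21,Olfactory_L,LS,L
22,Olfactory_R,LS,R
23,Frontal_Sup_Medial_L,DMN,L
24,Frontal_Sup_Medial_R,DMN,R
25,Frontal_Med_Orb_L,DMN,L
26,Frontal_Med_Orb_R,DMN,R
27,Rectus_L,DMN,L
28,Rectus_R,DMN,R
29,Insula_L,LS,L
30,Insula_R,LS,R
31,Cingulum_Ant_L,DMN,L
32,Cingulum_Ant_R,DMN,R
33,Cingulum_Mid_L,LS,L
34,Cingulum_Mid_R,LS,R
35,Cingulum_Post_L,DMN,L
36,Cingulum_Post_R,DMN,R
37,Hippocampus_L,LS,L
38,Hippocampus_R,LS,R
39,ParaHippocampal_L,LS,L
40,ParaHippocampal_R,LS,R
41,Amygdala_L,LS,L
42,Amygdala_R,LS,R
43,Calcarine_L,VN,L
44,Calcarine_R,VN,R
45,Cuneus_L,VN,L
46,Cuneus_R,VN,R
47,Lingual_L,VN,L
48,Lingual_R,VN,R
49,Occipital_Sup_L,VN,L
50,Occipital_Sup_R,VN,R
51,Occipital_Mid_L,VN,L
52,Occipital_Mid_R,VN,R
53,Occipital_Inf_L,VN,L
54,Occipital_Inf_R,VN,R
55,Fusiform_L,VN,L
56,Fusiform_R,VN,R
57,Postcentral_L,SMN,L
58,Postcentral_R,SMN,R
59,Parietal_Sup_L,SMN,L
60,Parietal_Sup_R,SMN,R
61,Parietal_Inf_L,FPN,L
62,Parietal_Inf_R,FPN,R
63,SupraMarginal_L,FPN,L
64,SupraMarginal_R,FPN,R
65,Angular_L,DMN,L
66,Angular_R,DMN,R
67,Precuneus_L,DMN,L
68,Precuneus_R,DMN,R
69,Paracentral_Lobule_L,SMN,L
70,Paracentral_Lobule_R,SMN,R
71,Caudate_L,LS,L
72,Caudate_R,LS,R
73,Putamen_L,LS,L
74,Putamen_R,LS,R
75,Pallidum_L,LS,L
76,Pallidum_R,LS,R
77,Thalamus_L,LS,L
78,Thalamus_R,LS,R
79,Heschl_L,SMN,L
80,Heschl_R,SMN,R
81,Temporal_Sup_L,SMN,L
82,Temporal_Sup_R,SMN,R
83,Temporal_Pole_Sup_L,LS,L
84,Temporal_Pole_Sup_R,LS,R
85,Temporal_Mid_L,DMN,L
86,Temporal_Mid_R,DMN,R
87,Temporal_Pole_Mid_L,LS,L
88,Temporal_Pole_Mid_R,LS,R
89,Temporal_Inf_L,DMN,L
90,Temporal_Inf_R,DMN,R
91,Cerebelum_Crus1_L,CERB,L
92,Cerebelum_Crus1_R,CERB,R
93,Cerebelum_Crus2_L,CERB,L
94,Cerebelum_Crus2_R,CERB,R
95,Cerebelum_3_L,CERB,L
96,Cerebelum_3_R,CERB,R
97,Cerebelum_4_5_L,CERB,L
98,Cerebelum_4_5_R,CERB,R
99,Cerebelum_6_L,CERB,L
100,Cerebelum_6_R,CERB,R
101,Cerebelum_7b_L,CERB,L
102,Cerebelum_7b_R,CERB,R
103,Cerebelum_8_L,CERB,L
104,Cerebelum_8_R,CERB,R
105,Cerebelum_9_L,CERB,L
106,Cerebelum_9_R,CERB,R
107,Cerebelum_10_L,CERB,L
108,Cerebelum_10_R,CERB,R
109,Vermis_1_2,CERB,M
110,Vermis_3,CERB,M
111,Vermis_4_5,CERB,M
112,Vermis_6,CERB,M
113,Vermis_7,CERB,M
114,Vermis_8,CERB,M
115,Vermis_9,CERB,M
116,Vermis_10,CERB,M
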