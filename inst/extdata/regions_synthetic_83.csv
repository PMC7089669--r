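region_id,name,lobe,hemisphere
0,left_superior_temporal_gyrus,temporal,left
1,right_superior_temporal_gyrus,temporal,right
2,left_middle_inferior_temporal_gyrus,temporal,left
3,right_middle_inferior_temporal_gyrus,temporal,right
4,left_fusiform_gyrus,temporal,left
5,right_fusiform_gyrus,temporal,right
6,left_parahippocampal_ambient_gyrus,temporal,left
7,right_parahippocampal_ambient_gyrus,temporal,right
8,left_hippocampus,temporal,left
9,right_hippocampus,temporal,right
10,left_amygdala,temporal,left
11,right_amygdala,temporal,right
12,left_anterior_temporal_lobe_medial,temporal,left
13,right_anterior_temporal_lobe_medial,temporal,right
14,left_anterior_temporal_lobe_lateral,temporal,left
15,right_anterior_temporal_lobe_lateral,temporal,right
16,left_posterior_temporal_lobe,temporal,left
17,right_posterior_temporal_lobe,temporal,right
18,left_superior_frontal_gyrus,frontal,left
19,right_superior_frontal_gyrus,frontal,right
20,left_middle_frontal_gyrus,frontal,left
21,right_middle_frontal_gyrus,frontal,right
22,left_inferior_frontal_gyrus,frontal,left
23,right_inferior_frontal_gyrus,frontal,right
24,left_precentral_gyrus,frontal,left
25,right_precentral_gyrus,frontal,right
26,left_anterior_orbital_gyrus,frontal,left
27,right_anterior_orbital_gyrus,frontal,right
28,left_posterior_orbital_gyrus,frontal,left
29,right_posterior_orbital_gyrus,frontal,right
30,left_medial_orbital_gyrus,frontal,left
31,right_medial_orbital_gyrus,frontal,right
32,left_lateral_orbital_gyrus,frontal,left
33,right_lateral_orbital_gyrus,frontal,right
34,left_gyrus_rectus,frontal,left
35,right_gyrus_rectus,frontal,right
36,left_subgenual_frontal_cortex,frontal,left
37,right_subgenual_frontal_cortex,frontal,right
38,left_postcentral_gyrus,parietal,left
39,right_postcentral_gyrus,parietal,right
40,left_superior_parietal_gyrus,parietal,left
41,right_superior_parietal_gyrus,parietal,right
42,left_inferior_parietal_lobule,parietal,left
43,right_inferior_parietal_lobule,parietal,right
44,left_precuneus,parietal,left
45,right_precuneus,parietal,right
46,left_paracentral_lobule,parietal,left
47,right_paracentral_lobule,parietal,right
48,left_lingual_gyrus,occipital,left
49,right_lingual_gyrus,occipital,right
50,left_cuneus,occipital,left
51,right_cuneus,occipital,right
52,left_lateral_occipital_lobe,occipital,left
53,right_lateral_occipital_lobe,occipital,right
54,left_insula,insula_cingulate,left
55,right_insula,insula_cingulate,right
56,left_anterior_cingulate_gyrus,insula_cingulate,left
57,right_anterior_cingulate_gyrus,insula_cingulate,right
58,left_posterior_cingulate_gyrus,insula_cingulate,left
59,right_posterior_cingulate_gyrus,insula_cingulate,right
60,left_subcallosal_area,insula_cingulate,left
61,right_subcallosal_area,insula_cingulate,right
62,left_caudate_nucleus,deep_nuclei,left
63,right_caudate_nucleus,deep_nuclei,right
64,left_nucleus_accumbens,deep_nuclei,left
65,right_nucleus_accumbens,deep_nuclei,right
66,left_putamen,deep_nuclei,left
67,right_putamen,deep_nuclei,right
68,left_pallidum,deep_nuclei,left
69,right_pallidum,deep_nuclei,right
70,left_thalamus,deep_nuclei,left
71,right_thalamus,deep_nuclei,right
72,left_substantia_nigra,deep_nuclei,left
73,right_substantia_nigra,deep_nuclei,right
74,left_ventral_diencephalon,deep_nuclei,left
75,right_ventral_diencephalon,deep_nuclei,right
76,left_cerebellar_hemisphere,cerebellum,left
77,right_cerebellar_hemisphere,cerebellum,right
78,left_dentate_nucleus,cerebellum,left
79,right_dentate_nucleus,cerebellum,right
80,midbrain,brainstem,midline
81,pons,brainstem,midline
82,medulla,brainstem,midline
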