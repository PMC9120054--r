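"region_index","name","hemisphere","category","family","lobe"
0,"lh_bankssts","left","cortical","none","temporal"
1,"lh_caudalanteriorcingulate","left","cortical","none","cingulate"
2,"lh_caudalmiddlefrontal","left","cortical","none","frontal"
3,"lh_cuneus","left","cortical","none","occipital"
4,"lh_entorhinal","left","cortical","none","temporal"
5,"lh_fusiform","left","cortical","none","temporal"
6,"lh_inferiorparietal","left","cortical","none","parietal"
7,"lh_inferiortemporal","left","cortical","none","temporal"
8,"lh_isthmuscingulate","left","cortical","none","cingulate"
9,"lh_lateraloccipital","left","cortical","none","occipital"
10,"lh_lateralorbitofrontal","left","cortical","none","frontal"
11,"lh_lingual","left","cortical","none","occipital"
12,"lh_medialorbitofrontal","left","cortical","none","frontal"
13,"lh_middletemporal","left","cortical","none","temporal"
14,"lh_parahippocampal","left","cortical","none","temporal"
15,"lh_paracentral","left","cortical","none","frontal"
16,"lh_parsopercularis","left","cortical","none","frontal"
17,"lh_parsorbitalis","left","cortical","none","frontal"
18,"lh_parstriangularis","left","cortical","none","frontal"
19,"lh_pericalcarine","left","cortical","none","occipital"
20,"lh_postcentral","left","cortical","none","parietal"
21,"lh_posteriorcingulate","left","cortical","none","cingulate"
22,"lh_precentral","left","cortical","none","frontal"
23,"lh_precuneus","left","cortical","none","parietal"
24,"lh_rostralanteriorcingulate","left","cortical","none","cingulate"
25,"lh_rostralmiddlefrontal","left","cortical","none","frontal"
26,"lh_superiorfrontal","left","cortical","none","frontal"
27,"lh_superiorparietal","left","cortical","none","parietal"
28,"lh_superiortemporal","left","cortical","none","temporal"
29,"lh_supramarginal","left","cortical","none","parietal"
30,"lh_frontalpole","left","cortical","none","frontal"
31,"lh_temporalpole","left","cortical","none","temporal"
32,"lh_transversetemporal","left","cortical","none","temporal"
33,"lh_insula","left","cortical","none","insula"
34,"lh_thalamus","left","subcortical","none","subcortical"
35,"lh_caudate","left","subcortical","none","subcortical"
36,"lh_putamen","left","subcortical","none","subcortical"
37,"lh_pallidum","left","subcortical","none","subcortical"
38,"lh_accumbens","left","subcortical","none","subcortical"
39,"lh_hippocampus_CA1","left","hippocampal_subfield","hippocampus","limbic"
40,"lh_hippocampus_CA3_4","left","hippocampal_subfield","hippocampus","limbic"
41,"lh_hippocampus_subicular_complex","left","hippocampal_subfield","hippocampus","limbic"
42,"lh_hippocampus_GC_DG","left","hippocampal_subfield","hippocampus","limbic"
43,"lh_amygdala_LA","left","amygdala_nucleus","amygdala","limbic"
44,"lh_amygdala_BA","left","amygdala_nucleus","amygdala","limbic"
45,"lh_amygdala_ABA","left","amygdala_nucleus","amygdala","limbic"
46,"lh_amygdala_CoA","left","amygdala_nucleus","amygdala","limbic"
47,"lh_amygdala_CeA","left","amygdala_nucleus","amygdala","limbic"
48,"lh_amygdala_CAT","left","amygdala_nucleus","amygdala","limbic"
49,"rh_bankssts","right","cortical","none","temporal"
50,"rh_caudalanteriorcingulate","right","cortical","none","cingulate"
51,"rh_caudalmiddlefrontal","right","cortical","none","frontal"
52,"rh_cuneus","right","cortical","none","occipital"
53,"rh_entorhinal","right","cortical","none","temporal"
54,"rh_fusiform","right","cortical","none","temporal"
55,"rh_inferiorparietal","right","cortical","none","parietal"
56,"rh_inferiortemporal","right","cortical","none","temporal"
57,"rh_isthmuscingulate","right","cortical","none","cingulate"
58,"rh_lateraloccipital","right","cortical","none","occipital"
59,"rh_lateralorbitofrontal","right","cortical","none","frontal"
60,"rh_lingual","right","cortical","none","occipital"
61,"rh_medialorbitofrontal","right","cortical","none","frontal"
62,"rh_middletemporal","right","cortical","none","temporal"
63,"rh_parahippocampal","right","cortical","none","temporal"
64,"rh_paracentral","right","cortical","none","frontal"
65,"rh_parsopercularis","right","cortical","none","frontal"
66,"rh_parsorbitalis","right","cortical","none","frontal"
67,"rh_parstriangularis","right","cortical","none","frontal"
68,"rh_pericalcarine","right","cortical","none","occipital"
69,"rh_postcentral","right","cortical","none","parietal"
70,"rh_posteriorcingulate","right","cortical","none","cingulate"
71,"rh_precentral","right","cortical","none","frontal"
72,"rh_precuneus","right","cortical","none","parietal"
73,"rh_rostralanteriorcingulate","right","cortical","none","cingulate"
74,"rh_rostralmiddlefrontal","right","cortical","none","frontal"
75,"rh_superiorfrontal","right","cortical","none","frontal"
76,"rh_superiorparietal","right","cortical","none","parietal"
77,"rh_superiortemporal","right","cortical","none","temporal"
78,"rh_supramarginal","right","cortical","none","parietal"
79,"rh_frontalpole","right","cortical","none","frontal"
80,"rh_temporalpole","right","cortical","none","temporal"
81,"rh_transversetemporal","right","cortical","none","temporal"
82,"rh_insula","right","cortical","none","insula"
83,"rh_thalamus","right","subcortical","none","subcortical"
84,"rh_caudate","right","subcortical","none","subcortical"
85,"rh_putamen","right","subcortical","none","subcortical"
86,"rh_pallidum","right","subcortical","none","subcortical"
87,"rh_accumbens","right","subcortical","none","subcortical"
88,"rh_hippocampus_CA1","right","hippocampal_subfield","hippocampus","limbic"
89,"rh_hippocampus_CA3_4","right","hippocampal_subfield","hippocampus","limbic"
90,"rh_hippocampus_subicular_complex","right","hippocampal_subfield","hippocampus","limbic"
91,"rh_hippocampus_GC_DG","right","hippocampal_subfield","hippocampus","limbic"
92,"rh_amygdala_LA","right","amygdala_nucleus","amygdala","limbic"
93,"rh_amygdala_BA","right","amygdala_nucleus","amygdala","limbic"
94,"rh_amygdala_ABA","right","amygdala_nucleus","amygdala","limbic"
95,"rh_amygdala_CoA","right","amygdala_nucleus","amygdala","limbic"
96,"rh_amygdala_CeA","right","amygdala_nucleus","amygdala","limbic"
97,"rh_amygdala_CAT","right","amygdala_nucleus","amygdala","limbic"
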