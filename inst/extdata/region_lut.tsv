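label_id	region_name
1	Right caudate + right putamen
2	Left caudate + left putamen
19	Right thalamus + right hypothalamus
20	Left thalamus + left hypothalamus
21	Right hippocampus
22	Left hippocampus
23	Right amygdala
24	Left amygdala
29	Right cerebellum
30	Left cerebellum
33	Right cingulate cortex
34	Left cingulate cortex
39	Right frontal cortex
40	Left frontal cortex
43	Right temporal cortex
44	Left temporal cortex
49	Right occipital cortex
50	Left occipital cortex
51	Right parietal cortex
52	Left parietal cortex
80	Right cortical white matter
81	Left cortical white matter
84	Brain stem
85	Right lateral ventricle
86	Left lateral ventricle
87	Third and fourth ventricles
88	Cerebellar white matter
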