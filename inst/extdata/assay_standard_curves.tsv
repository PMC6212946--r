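assay	role	slope	r2	efficiency_published
hsa-let-7a-5p	candidate_en	-3.292	0.991	101
hsa-miR-30d-5p	candidate_en	-3.371	0.996	98
hsa-miR-92a-3p	candidate_en	-3.549	0.994	91
hsa-miR-93-5p	candidate_en	-3.371	0.996	98
hsa-let-7f-5p	candidate_en	-3.626	0.985	89
hsa-miR-25-3p	candidate_en	-3.533	0.994	92
hsa-miR-26a-5p	candidate_en	-3.558	0.997	91
hsa-miR-21-5p	candidate_en	-3.516	0.994	92
hsa-miR-16-5p	candidate_en	-3.582	0.997	90
hsa-let-7g-5p	candidate_en	-3.338	0.959	99
hsa-miR-181a-5p	overexpressed_target	-3.872	0.966	81
hsa-miR-128-3p	overexpressed_target	-3.406	0.99	97
hsa-miR-20b-5p	overexpressed_target	-3.570	0.997	91
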