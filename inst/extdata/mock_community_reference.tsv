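taxon	species	genome_size	rrna_copies	vendor_expected_16s
Listeria	Listeria_monocytogenes	2992342	6	0.141
Pseudomonas	Pseudomonas_aeruginosa	6792330	4	0.042
Bacillus	Bacillus_subtilis	4045677	10	0.174
Escherichia	Escherichia_coli	4875441	7	0.101
Salmonella	Salmonella_enterica	4809318	7	0.104
Lactobacillus	Lactobacillus_fermentum	1905333	5	0.184
Enterococcus	Enterococcus_faecalis	2845392	4	0.099
Staphylococcus	Staphylococcus_aureus	2730326	6	0.155
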