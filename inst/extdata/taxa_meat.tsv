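species	strain	phylum	copy_number	copy_number_rank	genome_size_mb	gc_mol_percent	identity_pct
Brochothrix thermosphacta	RK8b	Bacillota	9	species	2.6	53.1	99.7
Staphylococcus condimenti	H13a	Bacillota	5.7	genus_mean	2.7	52.6	99.8
Rothia nasimurium	H14a	Actinomycetota	3	species	2.5	56.2	99.7
Serratia quinivorans	H25	Pseudomonadota	7	species	5.4	54.5	99.5
Acinetobacter guillouiae	R7a	Pseudomonadota	7	species	4.6	53.0	99.5
Proteus mirabilis	H1	Pseudomonadota	6.8	genus_mean	4.1	53.0	99.7
Pseudomonas weihenstephanensis	RK8a	Pseudomonadota	5.6	genus_mean	4.8	53.1	99.9
Pseudomonas petroselini	HK3a	Pseudomonadota	5.6	genus_mean	6.9	53.6	99.6
Pseudomonas helleri	HK4	Pseudomonadota	5.6	genus_mean	5.7	53.0	99.5
Pseudomonas gessardii	H4a	Pseudomonadota	5.6	genus_mean	6.5	53.5	99.9
Citrobacter gillenii	R22	Pseudomonadota	7.8	genus_mean	5.2	54.6	99.9
Acinetobacter pullicarnis	R25a	Pseudomonadota	6.7	genus_mean	4.1	52.7	98.2
Pantoea agglomerans	H6a	Pseudomonadota	7	species	4.7	55.5	99.0
Chryseobacterium shigense	H9a	Bacteroidota	3.7	genus_mean	4.9	50.2	99.2
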