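species	strain	phylum	copy_number	copy_number_rank	genome_size_mb	gc_mol_percent	identity_pct
Bacillus pumilus	M11	Bacillota	7.9	genus_mean	3.6	55.2	99.9
Enterococcus faecalis	M249	Bacillota	4	species	2.9	54.0	99.8
Lacticaseibacillus paracasei	M57	Bacillota	5	species	3.0	53.1	99.9
Staphylococcus cohnii	M34	Bacillota	6	species	2.7	51.3	99.9
Dermacoccus nishinomiyaensis	M293a	Actinomycetota	3	species	3.1	57.4	99.7
Gordonia paraffinivorans	M69	Actinomycetota	3.3	genus_mean	4.5	57.9	99.8
Kocuria salsicia	M239	Actinomycetota	3	species	3.1	57.3	99.8
Microbacterium oxydans	M29	Actinomycetota	2	species	3.9	56.0	99.1
Acinetobacter guillouiae	M9	Pseudomonadota	7	species	4.6	52.7	99.5
Pseudomonas koreensis	M92	Pseudomonadota	5.5	genus_mean	6.1	53.7	99.8
Escherichia coli	M159	Pseudomonadota	7	species	4.6	54.9	99.7
Stenotrophomonas lactitubi	M15	Pseudomonadota	3.4	genus_mean	4.9	54.9	100
Chryseobacterium shigense	M169	Bacteroidota	3.7	genus_mean	4.9	50.3	99.3
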