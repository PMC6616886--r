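genus_a	genus_b	max_inter_hcr	inter_pair	max_intra_hcr	intra_pair
Alicycliphilus	Acidovorax	0.521	GCF_000175235.1 & GCF_000204645.1	0.6	GCF_000175235.1 & GCF_002157165.1
Chlorobium	Chlorobaculum	0.324	GCF_000012585.1 & GCF_000006985.1	0.37	GCF_000012585.1 & GCF_000020645.1
Clostridium	Ruminiclostridium	0.192	GCF_000620945.1 & GCF_002161175.1	0.121	GCF_000620945.1 & GCF_000953215.1
Corynebacterium	Brevibacterium	0.228	GCF_000720035.1 & GCF_900184225.1	0.19	GCF_000720035.1 & GCF_001941505.1
Diaphorobacter	Acidovorax	0.515	GCF_000175235.1 & GCF_000015545.1	0.6	GCF_000175235.1 & GCF_002157165.1
Erythrobacter	Altererythrobacter	0.479	GCF_000013005.1 & GCF_900177715.1	0.493	GCF_000013005.1 & GCF_900115585.1
Histophilus	Haemophilus	0.481	GCF_002015075.1 & GCF_000027305.1	0.557	GCF_002015075.1 & GCF_000011785.1
Kluyvera	Enterobacter	0.598	GCF_000321045.1 & GCF_900168315.1	0.578	GCF_000321045.1 & GCF_001888805.2
Kluyvera	Escherichia	0.549	GCF_000759795.1 & GCF_900112785.1	0.506	GCF_000759795.1 & GCF_000350705.1
Lelliottia	Enterobacter	0.709	GCF_001652505.2 & GCF_001729725.1	0.702	GCF_001652505.2 & GCF_002811785.1
Pseudodesulfovibrio	Desulfovibrio	0.397	GCF_000422565.1 & GCF_000189295.2	0.397	GCF_000422565.1 & GCF_900188225.1
Roseburia	Clostridium	0.194	GCF_900111235.1 & GCF_001940165.1	0.2	GCF_900111235.1 & GCF_900112775.1
Serratia	Chania	0.575	GCF_001976145.1 & GCF_002588845.1	0.697	GCF_001976145.1 & GCF_000743365.1
Sphingomonas	Rhizorhabdus	0.33	GCF_000512205.2 & GCF_000715175.2	0.362	GCF_000512205.2 & GCF_001717955.1
Vibrio	Aliivibrio	0.312	GCF_002100145.1 & GCF_001691025.1	0.364	GCF_002100145.1 & GCF_000280885.2
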