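phylum_a	phylum_b	min_intra_hcr_a	max_inter_hcr	accession_a	accession_b
Proteobacteria	Bacteroidetes	0.015999617	0.151368772	GCA_002355135.1	GCA_000090965.1
Proteobacteria	Deferribacteres	0.015999617	0.112992155	GCA_000284355.1	GCA_000010985.1
Proteobacteria	Aquificae	0.015999617	0.112416204	GCA_000284355.1	GCA_000021545.1
Firmicutes	Dictyoglomi	0.026170854	0.170361824	GCA_000092965.1	GCA_000020965.1
Proteobacteria	Tenericutes	0.015999617	0.101309783	GCA_001262715.1	GCA_900016775.1
Proteobacteria	Firmicutes	0.015999617	0.096263109	GCA_000284355.1	GCA_000014125.1
Proteobacteria	Fusobacteria	0.015999617	0.093542786	GCA_000816185.1	GCA_001296125.1
Firmicutes	Deferribacteres	0.026170854	0.13067773	GCA_000165465.1	GCA_000010985.1
Proteobacteria	Cyanobacteria	0.015999617	0.077366777	GCA_000011465.1	GCA_000008885.1
Proteobacteria	Dictyoglomi	0.015999617	0.074348485	GCA_002220775.1	GCA_000021645.1
Firmicutes	Aquificae	0.026170854	0.119079275	GCA_000025645.1	GCA_000191045.1
Tenericutes	Firmicutes	0.024333677	0.106030272	GCA_001702115.1	GCA_002441935.1
Tenericutes	Fusobacteria	0.024333677	0.104966983	GCA_000439435.1	GCA_000024565.1
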