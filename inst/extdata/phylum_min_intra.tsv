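phylum	min_intra_hcr	accession_a	accession_b
Proteobacteria	0.015999617	GCA_001417865.2	GCA_001190755.1
Tenericutes	0.024333677	GCA_000186985.3	GCA_001886855.1
Firmicutes	0.026170854	GCA_900183405.1	GCA_001010825.1
Spirochaetes	0.048420481	GCA_001936255.1	GCA_000092845.1
Fusobacteria	0.140362380	GCA_002356455.1	GCA_000024565.1
Bacteroidetes	0.166804691	GCA_000348805.1	GCA_002369955.1
Cyanobacteria	0.216424948	GCA_000015705.1	GCA_000015665.1
Thermotogae	0.220607538	GCA_000953715.1	GCA_001941385.1
Aquificae	0.221942947	GCA_000021545.1	GCA_000191045.1
Dictyoglomi	0.749914757	GCA_000020965.1	GCA_000021645.1
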