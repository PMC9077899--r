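network	samples	nodes	edges	unique_nodes	unique_edges	clustering_coefficient
full	1415	7868	58415	NA	NA	0.281
GTEX_NORMAL	313	6957	54664	6813	53233	0.291
TCGA_NORMAL	110	1059	1370	36	21	0.000
TCGA_LUAD	489	542	652	530	600	0.002
TCGA_LUSC	503	1429	1729	1414	1694	0.062
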