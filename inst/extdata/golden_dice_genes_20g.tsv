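gene	direction	log2FC	q	delta_betweenness	delta_eigenvector	rank_b	rank_e	norm_b	norm_e	ensemble_score	excluded	exclusion_reason	final_rank
G0014	down	-0.747000990387	8.05167540915e-09	0	0.00277054129514	3	1	0.5	1	0.5	FALSE		1
G0012	down	-0.541297637846	2.79624076941e-06	0	0.00155015233736	3	2	0.5	0.75	0.375	FALSE		2
G0010	down	-0.221863244696	0.0129431382879	0	9.8376862212e-13	3	3	0.5	0.5	0.25	FALSE		3
G0006	up	0.170077495332	0.0652888419824	0	0	3	4.5	0.5	0.125	0.0625	TRUE	below mean centrality (all_below)	NA
G0020	up	0.518559971464	6.4674821472e-05	0	0	3	4.5	0.5	0.125	0.0625	TRUE	below mean centrality (all_below)	NA
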