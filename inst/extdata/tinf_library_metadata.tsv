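library_id	stage	region	n_sequences	n_residues	median_size	sra_accession
Arg-A	adult	Arg	38060109	10385270028	300	SRR1168894
Arg-N	nymph	Arg	39759543	11417825638	300	SRR1168938
BolCol-A	adult	BolCol	38418718	10546661014	300	SRR1168892
BolCol-N	nymph	BolCol	39223445	11258595763	300	SRR1168893
BolNat-A	adult	BolNat	38573948	10165647571	300	SRR1168890
BolNat-N	nymph	BolNat	48570803	13994680783	300	SRR1168891
Chile-A	adult	Chile	34269672	9102400847	300	SRR1168882
Chile-N	nymph	Chile	38866808	11069693781	300	SRR1168885
Peru-A	adult	Peru	38540450	9775095017	300	SRR1168888
Peru-N	nymph	Peru	41292975	11889399223	300	SRR1168889
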