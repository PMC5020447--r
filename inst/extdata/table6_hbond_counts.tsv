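category	mm	mh	mm_mh	frac_mm_printed	frac_mh_printed	all_bonds	n_residues
R_CC	10345	14690	25035	41.3	58.7	78700	19182
R_CE	1685	1898	3583	47.0	53.0	10652	2584
R_EC	3972	2303	6275	63.3	36.7	17052	3193
R_EE	15143	5732	20875	72.5	27.5	51286	10370
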