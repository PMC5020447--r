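chain	observed	predicted	q_c_printed
trypsin_inhibitor_1MCTI	CCCCECCCHHHCCCCCCEEC	EEEEECCCCCCCCCEEEECE	42.8
kinase_inhibitor_1ATPI	HHHCCCCCCCCC	HHCCCCCCCCCC	100
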