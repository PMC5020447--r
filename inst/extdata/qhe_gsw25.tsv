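model	q_he_error_printed
SSP_55	1.8
SSP_CV	4.2
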