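model	observed	pred_H	pred_E	pred_C	q_j	q3	sov_j	sov	mcc_j
SSP_CV	H	682	1	39	94.46	76.65	100	59.07	0.79
SSP_CV	E	58	352	136	64.47	76.65	66.04	59.07	0.65
SSP_CV	C	53	40	39	29.55	76.65	62.75	59.07	0.13
SSP_55	H	680	0	42	94.19	80.36	100	62.44	0.83
SSP_55	E	25	384	137	70.33	80.36	63.68	62.44	0.73
SSP_55	C	51	20	61	46.22	80.36	78.91	62.44	0.25
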