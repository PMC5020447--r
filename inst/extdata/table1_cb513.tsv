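model	observed	pred_H	pred_E	pred_C	q_j	q3	sov_j	sov	mcc_j
SSP_CV	H	16469	48	1840	89.72	82.03	83.14	79.46	0.82
SSP_CV	E	92	8804	2955	74.29	82.03	72.24	79.46	0.71
SSP_CV	C	2313	2032	17081	79.73	82.03	75.46	79.46	0.64
SSP_55	H	16333	62	1962	88.98	81.72	82.19	78.93	0.81
SSP_55	E	87	9001	2763	75.96	81.72	73.43	78.93	0.71
SSP_55	C	2288	2279	16859	78.69	81.72	74.5	78.93	0.63
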