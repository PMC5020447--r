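file	md5
qhe_gsw25.tsv	86ebfbb35173a76ae8572ae948f3624b
table1_cb513.tsv	1580d1400a75dbdba4b509c9c69a4ab6
table2_gsw25.tsv	527c6552b6c54da5f73532f3f2f966bc
table5_inhibitors.tsv	aec37443a1e252ee78da29c532eb8e54
table6_hbond_counts.tsv	de80e1eef8315edcf964384a5e91a182
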