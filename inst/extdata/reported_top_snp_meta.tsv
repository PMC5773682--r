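food	top_snp	or_set1	lo_set1	hi_set1	or_set2	lo_set2	hi_set2	or_meta_reported	p_meta_reported
peach	rs28359884	1.70	1.34	2.14	1.91	1.51	2.40	1.80	2.3e-12
shrimp	rs74995702	2.27	1.84	2.80	1.58	1.27	1.97	1.91	6.3e-17
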