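food	locus	allele	case_freq_step0	control_freq_step0	or_step0_reported	top_case_freq_step0	top_control_freq_step0	case_freq_step1_reported	control_freq_step1_reported	or_step1_reported
peach	DRB1	09:01	0.225	0.148	1.67	.	.	.	.	.
peach	DRB1	14:05	0.042	0.020	2.21	0.225	0.148	0.055	0.023	2.45
shrimp	DRB1	04:05	0.232	0.131	2.00	.	.	.	.	.
shrimp	DRB1	15:01	0.101	0.077	1.35	0.232	0.131	0.132	0.089	1.56
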