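variable	case_with	case_without	control_with	control_without	printed_p
coronary_artery_disease	7	19	3	16	0.481
hypertension	17	9	11	8	0.757
hyperlipidemia	9	17	6	13	1.00
diabetes	0	26	0	19	1.00
cancer_history	3	23	1	18	0.627
smoking	2	24	2	17	1.0
vitamin_supplements	23	3	12	7	0.07
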