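variable	case_mean	case_sd	case_n	control_mean	control_sd	control_n	printed_p
age_years	76.0	5.7	26	76.4	4.8	19	0.79
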