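patient	ms_status	enrichment	platform	n_mutations
patient_1	MSI	array	454	897
patient_2	MSS	array	454	124
patient_3	MSS	in_solution	SOLiD	65
patient_4	MSS	in_solution	SOLiD	74
patient_5	MSS	in_solution	SOLiD	76
patient_6	MSI	in_solution	SOLiD	532
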