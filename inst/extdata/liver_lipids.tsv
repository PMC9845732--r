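analyte	mean_ref	sem_ref	mean_trt	sem_trt	n_per_group	units
cholesterol	1.64	0.09	1.84	0.10	14	mg/g
triacylglycerols	14.22	0.68	23.60	1.59	14	mg/g
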