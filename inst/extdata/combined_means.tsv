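gene	mean_ref	sem_ref	mean_trt	sem_trt	n_per_group
Clock	1	0.10	1.92	0.22	70
Bmal1	1	0.14	0.42	0.07	70
Rev-erba	1	0.20	1.63	0.34	70
Per1	1	0.13	1.52	0.20	70
Per2	1	0.11	0.46	0.05	70
Cry1	1	0.12	2.55	0.41	70
Acaca	1	0.14	0.33	0.05	70
Fads1	1	0.04	1.36	0.05	70
Fads2	1	0.11	2.07	0.15	70
Fasn	1	0.14	0.41	0.06	70
Scd1	1	0.15	0.43	0.07	70
Srebf1	1	0.08	0.83	0.06	70
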