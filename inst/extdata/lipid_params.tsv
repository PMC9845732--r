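gene	parameter	reference	reference_se	treatment	treatment_se	difference	ci_lo	ci_hi
Acaca	amplitude	2.04	0.26	0.37	0.26	-1.67	-2.39	-0.95
Fasn	amplitude	1.93	0.24	0.62	0.24	-1.31	-1.98	-0.65
Fads1	amplitude	0.25	0.06	0.33	0.06	0.08	-0.08	0.24
Fads2	amplitude	0.78	0.11	0.78	0.11	0.01	-0.30	0.30
Scd1	amplitude	1.40	0.21	0.63	0.21	-0.77	-1.35	-0.18
Srebf1	amplitude	0.52	0.09	0.40	0.09	-0.13	-0.38	0.12
Acaca	acrophase	18.72	0.43	18.44	2.38	-0.28	-5.05	4.50
Fasn	acrophase	18.95	0.42	17.91	1.30	-1.04	-3.74	1.66
Fads1	acrophase	18.19	0.79	18.03	0.59	-0.16	-2.12	1.89
Fads2	acrophase	6.98	0.47	7.73	0.48	0.75	-0.58	2.08
Scd1	acrophase	18.73	0.51	18.37	1.11	-0.36	-2.78	2.06
Srebf1	acrophase	18.91	0.58	18.53	0.76	-0.39	-2.27	1.50
Acaca	mesor	1.88	0.17	0.62	0.17	-1.26	-1.74	-0.78
Fasn	mesor	1.75	0.16	0.76	0.16	-0.99	-1.44	-0.55
Fads1	mesor	0.89	0.04	1.22	0.04	0.32	0.21	0.43
Fads2	mesor	0.74	0.07	1.54	0.07	0.80	0.60	1.00
Scd1	mesor	1.42	0.14	0.61	0.14	-0.82	-1.21	-0.43
Srebf1	mesor	0.98	0.06	0.82	0.06	-0.16	-0.33	0.01
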