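gene	parameter	reference	reference_se	treatment	treatment_se	difference	ci_lo	ci_hi
Clock	amplitude	0.89	0.17	2.27	0.17	1.38	0.91	1.85
Bmal1	amplitude	13.09	1.16	1.55	1.06	-11.54	-14.64	-8.43
Rev-erba	amplitude	11.44	1.69	18.53	1.67	7.08	2.39	11.78
Per1	amplitude	0.59	0.15	1.03	0.14	0.44	0.03	0.85
Per2	amplitude	0.62	0.11	0.18	0.11	-0.44	-0.75	-0.14
Cry1	amplitude	1.44	0.42	4.59	0.42	3.15	1.98	4.32
Clock	acrophase	18.38	0.64	17.99	0.25	-0.38	-1.74	0.98
Bmal1	acrophase	18.08	0.30	21.76	2.70	3.68	-1.70	9.06
Rev-erba	acrophase	6.88	0.50	6.80	0.31	-0.08	-1.24	1.09
Per1	acrophase	7.45	0.88	8.23	0.51	0.78	-1.22	2.78
Per2	acrophase	7.25	0.60	7.55	2.06	0.30	-3.95	4.54
Cry1	acrophase	18.50	0.99	18.37	0.31	-0.14	-2.18	1.91
Clock	mesor	0.92	0.11	1.83	0.11	0.91	0.59	1.22
Bmal1	mesor	7.71	0.77	1.44	0.76	-6.27	-8.42	-4.13
Rev-erba	mesor	6.27	1.13	10.38	1.12	4.10	0.96	7.25
Per1	mesor	0.76	0.10	1.20	0.10	0.44	0.16	0.72
Per2	mesor	0.96	0.07	0.45	0.07	-0.52	-0.72	-0.31
Cry1	mesor	1.15	0.28	3.02	0.28	1.87	1.09	2.65
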