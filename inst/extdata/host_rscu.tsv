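# Published RSCU reference values: hv_mean = mean over the polyprotein
# coding sequences of four honeybee viruses (ABPV, CBPV, KBV, SBV);
# remaining columns are the host/vector species reference sets.
aa	codon	hv_mean	apis_mellifera	apis_cerana	vespa_velutina	varroa_destructor
F	UUU	1.25	1.58	1.44	1.39	1.29
F	UUC	0.75	0.42	0.56	0.61	0.71
L	UUA	1.62	3.07	2.51	1.83	1.40
L	UUG	1.52	1.03	1.10	0.90	1.16
L	CUU	0.94	0.78	0.96	1.20	1.07
L	CUC	0.94	0.25	0.52	1.09	0.63
L	CUA	0.61	0.60	0.56	0.61	0.92
L	CUG	0.38	0.27	0.35	0.37	0.82
I	AUU	1.23	1.28	1.36	1.12	1.15
I	AUC	0.74	0.33	0.45	0.55	0.69
I	AUA	1.03	1.38	1.19	1.33	1.16
V	GUU	1.46	1.60	1.48	1.31	1.29
V	GUC	0.69	0.41	0.57	0.70	0.78
V	GUA	1.12	1.49	1.22	1.25	1.11
V	GUG	0.74	0.50	0.72	0.75	0.82
S	UCU	1.54	1.57	1.48	2.05	1.17
S	UCC	0.95	0.47	0.75	0.70	0.68
S	UCA	1.46	1.94	1.42	0.99	1.16
S	UCG	0.48	0.58	1.06	1.08	0.90
S	AGU	0.99	1.00	0.84	0.75	1.08
S	AGC	0.58	0.44	0.45	0.44	1.02
P	CCU	1.26	1.12	1.18	1.37	1.21
P	CCC	0.60	0.40	0.69	0.75	0.69
P	CCA	1.54	1.92	1.36	1.14	1.25
P	CCG	0.60	0.56	0.77	0.74	0.86
T	ACU	1.20	1.21	1.03	0.93	1.07
T	ACC	0.73	0.33	0.51	0.56	0.71
T	ACA	1.42	1.98	1.54	1.42	1.33
T	ACG	0.65	0.48	0.92	1.10	0.90
A	GCU	1.49	1.10	1.02	1.04	1.23
A	GCC	0.75	0.43	0.65	0.63	0.80
A	GCA	1.26	1.87	1.38	1.34	1.21
A	GCG	0.50	0.59	0.95	0.99	0.76
Y	UAU	1.44	1.71	1.60	1.49	1.24
Y	UAC	0.56	0.29	0.40	0.51	0.76
H	CAU	1.22	1.58	1.36	1.27	1.18
H	CAC	0.78	0.42	0.64	0.73	0.82
Q	CAA	1.28	1.60	1.52	1.42	1.16
Q	CAG	0.72	0.40	0.48	0.58	0.84
N	AAU	1.26	1.67	1.58	1.40	1.16
N	AAC	0.74	0.33	0.42	0.60	0.84
K	AAA	1.16	1.70	1.60	1.47	1.32
K	AAG	0.84	0.30	0.40	0.53	0.68
D	GAU	1.26	1.63	1.53	1.36	1.15
D	GAC	0.74	0.37	0.47	0.64	0.85
E	GAA	1.26	1.67	1.48	1.14	1.30
E	GAG	0.74	0.33	0.52	0.86	0.70
C	UGU	1.16	1.44	1.33	1.34	1.14
C	UGC	0.84	0.56	0.67	0.66	0.86
R	CGU	0.96	0.69	0.98	1.00	1.09
R	CGC	0.93	0.34	0.56	0.48	0.78
R	CGA	1.06	1.10	1.41	1.17	1.11
R	CGG	0.47	0.24	0.44	0.36	0.66
R	AGA	1.72	3.08	1.96	2.32	1.44
R	AGG	0.86	0.54	0.64	0.67	0.92
G	GGU	0.97	1.20	0.93	1.03	1.11
G	GGC	0.71	0.62	0.63	0.61	1.07
G	GGA	1.76	1.79	1.74	1.62	1.13
G	GGG	0.56	0.39	0.70	0.74	0.70
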