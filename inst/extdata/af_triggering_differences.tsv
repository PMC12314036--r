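protein	inflammation	structural_remodeling_fibrosis	electrophysiology_ectopic_activity	autonomic_ns_remodeling	raas_overactivation	drug
HCK	-0.40	1.27	0.10	-0.06	-0.31	I
FGR	-0.32	1.05	0.17	-0.06	-0.29	I
LYN	-0.45	1.02	0.30	-0.06	-0.32	I
ERBB4	-0.56	0.91	0.63	-0.36	-0.55	I/A
FYN	-0.20	0.75	0.10	-0.80	-0.32	I
TEC	-0.10	0.43	0.30	-0.15	-0.04	I/A
FLT3	-0.62	0.24	0.18	-0.06	-0.29	I
YES1	-0.02	0.23	0.04	-0.06	-0.01	I
CSK	-1.27	-0.09	-1.30	0.43	-0.04	I
SRC	-1.48	-2.88	0.37	-1.79	-0.50	I
BMX	-0.27	-0.17	-0.12	0.04	0.00	I/A
LIMK1	0.00	0.00	0.00	0.00	0.00	A
ITK	0.00	0.11	0.16	-0.17	0.00	I
PTK6	0.11	-0.20	-0.03	-0.01	-0.01	I
TXK	0.01	-0.06	0.00	-0.27	0.00	I
JAK3	-0.93	-0.39	0.12	-0.16	-0.26	I
BTK	-0.41	-0.58	-0.04	-0.30	-0.66	I/A
LCK	-1.45	-0.13	0.02	-0.15	-0.28	I
BLK	-1.78	-0.60	-0.63	0.05	-0.17	I
ERBB2	-1.28	-1.21	-0.23	-0.26	-0.51	I
EGFR	-1.16	-2.25	-0.65	-0.16	-0.62	I
RIPK2	-1.95	-2.48	-0.92	-0.07	-0.40	I/A
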