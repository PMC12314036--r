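protein	inflammation	oxidative_stress_endothelial_dysfunction	sympathetic_ns_overactivation	raas_overactivation	drug
ERBB4	0.24	0.60	-0.29	-0.30	I/A
ERBB2	0.01	1.39	-0.18	-1.30	I
RIPK2	-1.62	1.30	-0.21	0.18	I/A
BLK	-1.40	0.80	-0.27	-0.11	I
SRC	-0.79	0.43	-0.46	-0.35	I
LCK	0.27	-0.36	-0.15	-0.52	I
JAK3	0.40	-0.63	-0.24	-0.51	I
FLT3	0.26	-0.79	-0.12	-0.60	I
CSK	-1.15	0.25	-0.04	1.14	I
LIMK1	0.00	0.00	0.00	0.00	A
TXK	0.00	-0.06	0.00	0.02	I
PTK6	0.06	-0.09	-0.01	-0.19	I
YES1	-0.21	-0.12	-0.02	-0.13	I
ITK	-0.01	-0.19	0.04	-0.09	I
LYN	-0.01	-0.43	-0.15	-0.65	I
EGFR	-0.56	-0.46	-0.20	-1.72	I
BTK	-1.36	-0.47	0.00	-0.48	I/A
TEC	-0.01	-0.49	-0.04	-0.46	I/A
BMX	-0.37	-0.58	0.03	0.03	I/A
FYN	-1.04	-0.60	0.11	-0.24	I
FGR	-0.02	-0.67	-0.12	-0.45	I
HCK	-0.23	-0.71	-0.12	-0.47	I
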