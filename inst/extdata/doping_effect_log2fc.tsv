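marker	D2	D3	D4	D5	P1	P2	P3
ALAS2	0.86	0.95	0.80	0.70	-0.82	-1.32	-1.18
BCL2L1	0.71	0.81	0.79	0.69	-0.67	-0.88	-0.89
DCAF12	0.60	0.78	0.73	0.66	-0.59	-0.90	-0.89
EPB42	0.86	0.98	0.88	0.76	-0.89	-1.25	-1.08
GMPR	0.81	0.94	0.79	0.68	-0.72	-0.94	-0.84
OSBP2	0.96	1.08	1.05	1.00	-0.89	-1.16	-1.03
SELENBP1	0.98	1.09	0.97	0.83	-0.90	-1.19	-1.05
SLC4A1	0.89	1.08	0.96	0.82	-0.87	-1.18	-1.10
TMOD1	0.65	0.89	0.76	0.61	-0.71	-1.06	-1.00
TNS1	0.84	1.10	0.98	0.87	-0.94	-1.22	-1.10
TRIM58	0.73	0.82	0.72	0.67	-0.74	-0.94	-0.97
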