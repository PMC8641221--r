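measure	unit	control_mean	control_sd	control_n	treatment_mean	treatment_sd	treatment_n	printed_p
age	years	11.70	6.42	5	15.70	5.62	5	0.325
body_weight	kg	5.54	0.78	5	5.44	1.46	5	0.894
waist	cm	36.36	4.34	5	36.46	9.56	5	0.984
crp	ng/ul	6.75	4.26	5	14.63	11.70	5	0.195
sbp	mmHg	123.76	26.17	5	100.08	9.46	5	0.094
dbp	mmHg	71.08	16.43	5	65.80	13.13	5	0.590
insulin	U/L	28.91	14.30	5	41.93	16.79	5	0.223
homa	AU	2.67	2.02	5	9.08	10.88	5	0.231
glucose	mg/dL	33.80	18.85	5	73.80	61.34	5	0.201
total_cholesterol	mg/dL	145.40	23.14	5	220.60	62.56	5	0.036
triglycerides	mg/dL	44.00	9.14	5	75.60	65.58	5	0.317
ast	U/L	41.00	11.40	5	65.40	26.10	5	0.092
alt	U/L	71.00	54.99	5	286.20	115.47	5	0.006
alp	U/L	98.80	27.26	5	147.80	27.09	5	0.021
ggtp	U/L	32.20	8.14	5	84.00	38.76	5	0.019
liver_tg	mg/ug prot	41.80	14.99	5	43.80	25.72	5	0.884
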