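# Reference 12-class MI confusion matrix: classifier on measured lead-I features (26080 beats).
# Columns after HC are the published per-class metric values used as golden checks.
class	AMI	ALMI	ASMI	ASLMI	IMI	ILMI	IPMI	IPLMI	LMI	PMI	PLMI	HC	total	acc_ref	sen_ref	spe_ref
AMI	1453	255	150	0	335	228	21	97	44	2	39	176	2800	90.55	51.89	95.2
ALMI	154	1295	219	54	228	141	37	57	2	128	129	90	2534	91.33	51.1	95.66
ASMI	273	217	1563	25	605	555	41	101	129	10	125	470	4114	85.28	37.99	94.13
ASLMI	0	0	0	134	0	0	0	0	0	0	0	0	134	99.4	100	99.4
IMI	219	279	404	65	1748	372	72	144	51	35	177	1003	4569	80.87	38.26	89.93
ILMI	173	82	113	0	281	1723	26	204	122	3	5	411	3143	86.19	54.82	90.49
IPMI	5	8	3	0	9	0	310	0	0	0	0	1	336	99.09	92.26	99.18
IPLMI	31	68	77	1	84	155	2	449	53	1	19	123	1063	93.95	42.24	96.15
LMI	2	0	0	0	0	1	0	0	156	0	0	0	159	98.12	98.11	98.12
PMI	0	0	0	0	0	0	0	0	0	137	0	0	137	99.24	100	99.23
PLMI	0	1	1	0	7	3	0	5	0	0	261	10	288	96.92	90.63	97
HC	260	111	322	11	618	726	12	356	87	20	281	3999	6803	80.49	58.78	88.15
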