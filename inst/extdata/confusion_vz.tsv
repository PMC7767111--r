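# Reference 12-class MI confusion matrix: classifier on derived Frank Z lead features.
class	AMI	ALMI	ASMI	ASLMI	IMI	ILMI	IPMI	IPLMI	LMI	PMI	PLMI	HC	total	acc_ref	sen_ref	spe_ref
AMI	2228	74	272	1	76	24	8	14	5	6	9	83	2800	95.76	79.57	97.7
ALMI	45	2245	96	0	38	11	18	7	1	2	1	70	2534	97.58	88.6	98.54
ASMI	103	76	3591	2	105	87	4	13	0	0	0	133	4114	95.41	87.29	96.93
ASLMI	0	0	0	134	0	0	0	0	0	0	0	0	134	99.99	100	99.99
IMI	147	94	186	0	3379	254	18	80	14	3	28	366	4569	92.08	73.95	95.93
ILMI	18	17	35	0	202	2619	2	109	11	2	10	118	3143	94.69	83.33	96.25
IPMI	7	3	1	0	5	5	313	1	0	0	0	1	336	99.7	93.15	99.78
IPLMI	3	2	3	0	137	31	3	870	0	0	0	14	1063	97.67	81.84	98.34
LMI	0	0	0	0	2	0	0	1	156	0	0	0	159	99.83	98.11	99.84
PMI	0	0	0	0	0	0	0	0	0	137	0	0	137	99.89	100	99.89
PLMI	0	0	0	0	0	0	0	6	3	0	279	0	288	99.76	96.88	99.79
HC	212	77	82	0	311	448	3	184	8	15	6	5457	6803	91.83	80.21	95.93
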