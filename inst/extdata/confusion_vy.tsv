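# Reference 12-class MI confusion matrix: classifier on derived Frank Y lead features.
class	AMI	ALMI	ASMI	ASLMI	IMI	ILMI	IPMI	IPLMI	LMI	PMI	PLMI	HC	total	acc_ref	sen_ref	spe_ref
AMI	2232	44	113	0	137	55	4	32	5	32	4	142	2800	95.73	79.71	97.66
ALMI	35	2207	49	15	87	25	3	9	0	34	1	69	2534	96.68	87.1	97.72
ASMI	161	78	3111	9	176	103	12	25	0	0	36	403	4114	93.6	75.62	96.96
ASLMI	0	1	0	132	0	0	0	0	0	0	1	0	134	99.89	98.51	99.9
IMI	95	116	157	2	3702	136	6	72	12	2	38	231	4569	93.49	81.02	96.14
ILMI	8	15	50	1	130	2645	4	21	26	0	3	240	3143	95.82	84.16	97.41
IPMI	3	0	4	0	5	1	319	0	0	0	0	4	336	99.78	94.94	99.84
IPLMI	26	7	5	0	43	27	2	939	2	1	0	11	1063	98.76	88.33	99.2
LMI	0	0	0	0	0	0	0	0	159	0	0	0	159	99.69	100	99.68
PMI	0	0	0	0	0	0	0	0	0	137	0	0	137	99.51	100	99.51
PLMI	0	1	0	0	0	2	0	0	0	0	285	0	288	99.65	98.96	99.65
HC	217	276	289	0	252	244	10	40	37	58	6	5374	6803	90.3	78.99	94.29
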