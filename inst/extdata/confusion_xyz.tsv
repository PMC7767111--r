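# Reference 12-class MI confusion matrix: classifier on all three derived Frank leads (52 features).
class	AMI	ALMI	ASMI	ASLMI	IMI	ILMI	IPMI	IPLMI	LMI	PMI	PLMI	HC	total	acc_ref	sen_ref	spe_ref
AMI	2762	5	9	0	7	4	0	1	0	0	3	9	2800	99.72	98.64	99.85
ALMI	10	2504	6	0	2	2	2	0	1	0	0	7	2534	99.78	98.82	99.88
ASMI	9	12	4078	1	6	2	3	3	0	0	0	0	4114	99.73	99.12	99.85
ASLMI	0	0	0	134	0	0	0	0	0	0	0	0	134	100	100	100
IMI	5	3	4	0	4528	11	1	7	0	0	4	6	4569	99.7	99.1	99.83
ILMI	3	3	8	0	3	3119	1	1	1	0	1	3	3143	99.8	99.24	99.88
IPMI	3	0	0	0	3	0	329	0	0	0	0	1	336	99.94	97.92	99.97
IPLMI	2	3	3	0	6	8	0	1039	0	1	0	1	1063	99.85	97.74	99.94
LMI	0	0	0	0	0	0	0	0	159	0	0	0	159	99.99	100	99.99
PMI	0	0	0	0	0	0	0	0	0	137	0	0	137	99.99	100	99.99
PLMI	0	0	0	0	0	0	0	1	0	0	287	0	288	99.97	99.65	99.97
HC	2	2	4	0	10	1	1	1	0	1	0	6781	6803	99.81	99.68	99.86
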