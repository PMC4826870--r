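patient_id	age	day_1	day_2	day_3	day_4	day_5	mi_1	mi_2	mi_3	mi_4	mi_5	nihss_1	nihss_2	nihss_3	nihss_4	nihss_5
1	42	4	13	32	147	354	33	88	130	190	190	10	3	2	0	0
2	48	1	12	35	88	301	0	14	19	82	95	14	11	10	8	5
3	53	2	16	34	97	350	14	58	88	113	113	8	6	3	2	2
4	52	0	14	30	92	369	141	183	198	198	198	5	2	2	0	0
5	51	4	13	27	93	411	14	37	47	88	116	10	8	8	5	2
6	50	-	11	33	93	432	-	86	138	179	183	-	6	5	2	1
7	55	6	12	31	60	-	37	53	91	102	-	8	7	5	3	-
8	41	4	13	29	111	375	0	14	33	78	83	15	13	13	6	6
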