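sample_id	sex	age	microarray	qrt_pcr	tumor_type	who_grade
524	M	34	9.57	7.17e-4	glioblastoma	IV
427	M	59	11.79	2.98e-4	glioblastoma	IV
433	F	70	11.88	1.77e-4	glioblastoma	IV
409	M	57	11.13	2.67e-5	glioblastoma	IV
426	F	61	10.97	8.31e-5	glioblastoma	IV
417	M	56	11.48	4.87e-5	glioblastoma	IV
463	F	65	9.88	4.15e-5	glioblastoma	IV
018	M	79	10.14	NA	glioblastoma	IV
461	M	16	11.26	NA	glioblastoma	IV
369	F	65	10.42	NA	glioblastoma	IV
460	F	58	9.62	NA	glioblastoma	IV
366	M	40	9.96	3.23e-4	anaplastic ependymoma	III
140	F	27	11.08	NA	anaplastic astrocytoma	III
079	F	40	12.50	NA	astrocytoma	II
403	M	19	10.28	NA	gemistocytic astrocytoma	II
360	M	49	3.94	7.73e-5	meningioma	I
501	F	71	8.95	7.72e-5	meningioma	I
549	F	66	6.55	5.96e-5	meningioma	I
048	F	78	5.73	3.39e-5	meningioma	I
521	F	88	7.77	3.28e-5	meningioma	I
514	F	46	7.56	2.74e-5	meningioma	I
169	M	66	8.00	1.90e-5	meningioma	I
167	F	35	6.99	9.98e-6	meningioma	I
456	M	52	7.08	4.14e-6	meningioma	I
384	M	49	5.35	3.89e-6	meningioma	I
476	F	65	7.57	0	meningioma	I
455	F	60	8.89	NA	meningioma	I
367	F	37	3.92	NA	meningioma	I
394	F	62	7.23	NA	meningioma	I
502	M	72	3.18	NA	meningioma	I
075	M	20	11.34	NA	pilocytic astrocytoma	I
537	F	71	6.76	2.64e-5	haemangioblastoma	I
449	M	70	6.10	2.68e-4	metastatic adenocarcinoma	metastatic
408	M	67	4.66	4.64e-5	metastatic adenocarcinoma	metastatic
210	F	69	7.91	1.44e-5	metastatic adenocarcinoma	metastatic
153	F	58	9.91	4.20e-5	metastatic adenocarcinoma	metastatic
536	M	73	5.33	1.43e-5	metastatic adenocarcinoma	metastatic
166	F	56	6.14	NA	metastatic adenocarcinoma	metastatic
475	M	60	8.13	NA	metastatic adenocarcinoma	metastatic
398	F	73	8.78	NA	metastatic adenocarcinoma	metastatic
211	F	65	9.22	NA	metastatic adenocarcinoma	metastatic
438	M	61	6.99	NA	metastatic large cell carcinoma	metastatic
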