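joint_snp	chrom	bp	or	ci_low	ci_high	p
rs11368313	1	20141882	3.59	2.37	5.43	1.56e-9
rs111335312	3	41777743	1.69	1.41	2.03	1.13e-8
rs111723274	3	151675513	1.63	1.38	1.92	8.25e-9
rs1093873	4	8676148	3.48	2.22	5.44	4.68e-8
rs10006825	4	26153727	2.22	1.68	2.92	1.37e-8
rs10940110	5	66794814	2.22	1.74	2.83	1.18e-10
rs10514061	5	75435368	1.45	1.27	1.65	4.19e-8
rs10658790	6	126275488	1.59	1.36	1.86	6.29e-9
rs10253191	7	67372454	2.47	1.78	3.41	4.76e-8
rs112048508	10	30443336	1.72	1.42	2.08	2.81e-8
rs10567579	10	134807240	1.71	1.41	2.06	2.62e-8
rs10628082	11	134612753	1.78	1.47	2.15	2.39e-9
rs10840622	12	122288202	1.74	1.44	2.10	6.40e-9
rs111792251	13	40895225	2.06	1.63	2.62	2.07e-9
rs111282782	16	84564132	2.18	1.65	2.88	3.87e-8
rs111362005	17	831933	3.84	2.38	6.20	3.44e-8
rs1024819	17	55607271	2.98	2.08	4.28	3.02e-9
rs10163481	17	75148741	1.83	1.55	2.15	6.37e-13
rs10543240	18	42189616	1.69	1.41	2.01	5.06e-9
rs10420324	19	54469051	4.40	2.68	7.22	4.87e-9
rs1051904	20	4163302	1.76	1.46	2.12	3.22e-9
rs111797554	20	56168743	2.18	1.66	2.85	1.52e-8
rs1045588	22	18271078	3.12	2.11	4.63	1.46e-8
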