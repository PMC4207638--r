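chrom	n_cnvr	shared	private	novel	gains	losses	complex	genic	intergenic	subtelomeric	mean_size	cnvr_length	chrom_length	enrichment_pct
chr1	21	8	13	9	2	17	2	14	7	0	241828	5078379	185838109	2.73
chr2	13	3	10	5	5	7	1	9	4	1	69711	906246	120857687	0.75
chr3	14	3	11	3	3	11	0	11	3	0	80328	1124591	119479920	0.94
chr4	9	4	5	3	1	8	0	7	2	0	119780	1078019	108569075	0.99
chr5	7	5	2	2	3	3	1	4	3	2	60379	422653	99680356	0.42
chr6	11	5	6	3	1	9	1	9	2	0	206650	2273151	84719076	2.68
chr7	12	4	8	3	2	8	2	8	4	0	119155	1429861	98542428	1.45
chr8	9	5	4	1	4	5	0	8	1	1	170025	1530227	94057673	1.63
chr9	14	6	8	11	5	8	1	4	10	1	45785	640986	83561422	0.77
chr10	16	7	9	7	4	12	0	13	3	1	72954	1167268	83980604	1.39
chr11	2	0	2	1	0	2	0	2	0	0	5235	10470	61308211	0.02
chr12	6	5	1	1	0	3	3	5	1	0	538645	3231871	33091231	9.77
chr13	5	2	3	1	1	3	1	5	0	0	23837	119184	42578167	0.28
chr14	8	3	5	3	5	3	0	5	3	1	55523	444184	93904894	0.47
chr15	2	0	2	2	0	2	0	2	0	0	80429	160857	91571448	0.18
chr16	5	3	2	4	0	5	0	4	1	0	46120	230599	87365405	0.26
chr17	6	2	4	3	1	5	0	3	3	0	100527	603159	80757907	0.75
chr18	8	4	4	4	2	6	0	5	3	0	59831	478649	82527541	0.58
chr19	6	1	5	5	1	5	0	2	4	0	69818	418908	59975221	0.70
chr20	19	11	8	4	5	14	0	13	6	0	102575	1948920	64166202	3.04
chr21	2	1	1	1	0	1	1	2	0	1	230842	461684	57723302	0.80
chr22	4	2	2	1	1	3	0	2	2	0	48296	193182	49946797	0.39
chr23	8	2	6	4	1	6	1	5	3	0	122812	982492	55726280	1.76
chr24	4	1	3	2	1	3	0	3	1	0	104966	419862	46749900	0.90
chr25	3	2	1	1	0	2	1	2	1	0	46573	139720	39536964	0.35
chr26	6	4	2	3	1	5	0	2	4	0	105913	635479	41866177	1.52
chr27	2	1	1	0	0	1	1	2	0	0	15084	30168	39960074	0.08
chr28	4	2	2	2	1	3	0	2	2	0	37557	150227	46177339	0.33
chr29	3	2	1	2	1	2	0	3	0	0	250105	750316	33672925	2.23
chr30	4	1	3	2	2	2	0	2	2	0	67956	271825	30062385	0.90
chr31	2	1	1	2	0	2	0	0	2	1	34286	68572	24984650	0.27
chrX	12	5	7	10	4	7	1	0	12	1	87146	1045753	124114077	0.84
chrUn	11	9	2	11	6	0	5	0	11	0	4118	45298	117461955	0.04
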