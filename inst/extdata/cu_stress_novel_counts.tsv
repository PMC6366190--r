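id	sequence	ck	ck_std	cu	cu_std	log2fc	pvalue	sig_label	regulation
novel_mir_11	TAACTCTGAGTATAAGGCACC	131	12.3805	35	3.551	-1.801772	5.42e-13	**	down
novel_mir_14	TCATGTCTTAATGAATTGCCT	21	1.9847	0	0.01	-7.632777	1.03e-06	**	down
novel_mir_15	TATGGACTTCTCTTAACCCTGT	12	1.1341	0	0.01	-6.825404	0.000384	**	down
novel_mir_17	ATTCGAACTCAAGACTAAGGT	6104	576.8758	0	0.01	-15.81597	0	**	down
novel_mir_2	TTGAGAGTGATTTTAGAAAAT	127	12.0025	17	1.7248	-2.798834	1.43e-20	**	down
novel_mir_20	TTCATGGACGTTGATAAGATCCT	6994	660.9878	7626	773.7094	0.2271682	1.79e-21	ns	none
novel_mir_22	TTCCCAATGCCGCCCATTCCAA	5598	529.0549	0	0.01	-15.69113	0	**	down
novel_mir_23	AGGCAGTCACCTTGGCTAACT	15	1.4176	0	0.01	-7.147307	5.33e-05	**	down
novel_mir_24	TTCTTGTGATCTTGTTGTTTC	620	58.5949	0	0.01	-12.51656	5.74e-178	**	down
novel_mir_25	TGAACTCCATCCTTTGAATGA	21	1.9847	0	0.01	-7.632777	1.03e-06	**	down
novel_mir_26	TTGGGATTGAGCCTTATGGGC	27	2.5517	8	0.8117	-1.65244	0.0024307	**	down
novel_mir_29	TTGACATCGATGATATTGAGG	15	1.4176	0	0.01	-7.147307	5.33e-05	**	down
novel_mir_30	TTGTAGGAGCCACAAAATTCTGT	18	1.7011	0	0.01	-7.410324	7.40e-06	**	down
novel_mir_31	TATTCCTTGATATTGCATGTT	27	2.5517	0	0.01	-7.995315	1.98e-08	**	down
novel_mir_37	GTTGGAAGCCGGTGGGGGACC	847	80.0481	218	22.1176	-1.855672	9.22e-79	**	down
novel_mir_38	GTTGGAAGTCGGTGGGGGAAC	209	19.7521	34	3.4495	-2.517547	1.70e-29	**	down
novel_mir_39	GTTGGAAGTCGGTGGGGGACC	373	35.2514	82	8.3195	-2.083112	3.23e-41	**	down
novel_mir_4	CAATCAGCGGCTGAGATAAGC	13	1.2286	0	0.01	-6.940871	0.0001988	**	down
novel_mir_41	TTCCACGGCTTTCTTGAACTT	2122	200.5456	707	71.7299	-1.483284	5.76e-142	**	down
novel_mir_42	TCTTACCAACACCTCCCATTCC	19277	1821.8276	6256	634.7136	-1.521209	0	**	down
novel_mir_43	TTCCCAAGACCCCCCATGCCAA	14146	1336.9079	3601	365.3459	-1.871565	0	**	down
novel_mir_44	AGTTACTAATTCATGATGTGGC	20	1.8902	11	1.116	-0.760202	0.1625223	ns	none
novel_mir_45	CGGTCCTGGGCCTCTGGCCTT	124	11.719	12	1.2175	-3.266856	3.59e-23	**	down
novel_mir_46	TTCCCACGGCTTTCTTGAACT	21	1.9847	0	0.01	-7.632777	1.03e-06	**	down
novel_mir_48	CTTGAACTCCAATTTGCACCC	117	11.0574	0	0.01	-10.1108	3.67e-34	**	down
novel_mir_5	CTTCTTATTCTTTAAAAGGACT	14	1.3231	0	0.01	-7.047778	0.0001029	**	down
novel_mir_50	TAACAACTTAAGCTTTTGGGT	23	2.1737	6	0.6087	-1.83635	0.0027137	**	down
novel_mir_53	AAGGAATTACAAAAGAAATTC	25	2.3627	0	0.01	-7.884293	7.37e-08	**	down
novel_mir_54	TTGCCACTGAGTCTAGAGATG	11	1.0396	0	0.01	-6.699885	0.0007418	**	down
novel_mir_57	TTACACAGAGAGATGACGGTGG	37	3.4968	16	1.6233	-1.107106	0.0084634	**	down
novel_mir_60	AGAAGAGAGAGAGTACAGCTA	20	1.8902	13	1.3189	-0.519204	0.3201281	ns	none
novel_mir_61	CATTATGTTGATTTCTTTGTT	94	8.8837	45	4.5656	-0.960356	0.000165	ns	none
novel_mir_62	TTTTGTTGCTGGTCATCTAGTC	230	21.7368	0	0.01	-11.08592	1.82e-66	**	down
novel_mir_63	TTCTATCGTCATCCTTCCTTG	25	2.3627	10	1.0146	-1.219525	0.0202609	*	down
novel_mir_64	TTGACTTTGGTGTTTTGGACC	19	1.7956	0	0.01	-7.488322	3.83e-06	**	down
novel_mir_66	TGTGGACATTGTTTCAGGGCT	39	3.6858	23	2.3335	-0.659482	0.0812967	ns	none
novel_mir_7	CCCTTTGGAAGTGCTAAGCGCC	13	1.2286	0	0.01	-6.940871	0.0001988	**	down
novel_mir_70	CATGTGCCCCTCTTCCCCATC	55	5.1979	9	0.9131	-2.509084	1.06e-08	**	down
novel_mir_72	CATCGTCCGAGGCTATGGCGG	11	1.0396	0	0.01	-6.699885	0.0007418	**	down
novel_mir_73	TGAGATTGAAGACTTTGATGT	326	30.8096	58	5.8845	-2.388388	1.43e-42	**	down
novel_mir_76	ACAAGACTTAGGAAGAATGCACC	1038	98.0991	787	79.8465	-0.297011	1.24e-05	ns	none
novel_mir_77	CATATCATGCTCTTTAGGACT	0	0.01	14	1.4204	7.1501535	3.55e-05	**	up
novel_mir_79	CTCGTGATGTCAATGATCTCA	0	0.01	14	1.4204	7.1501535	3.55e-05	**	up
novel_mir_80	TTGCCGCACGAGAGATGGCACC	0	0.01	39	3.9568	8.6281903	4.29e-13	**	up
novel_mir_81	TCCCAATGCCGCCCATTCCAA	0	0.01	2343	237.7132	14.536934	0	**	up
novel_mir_83	CACAAACGACTCTCGGCAACGGA	0	0.01	6829	692.8483	16.080252	0	**	up
novel_mir_86	TATTCCTTGATATTGCATGTTT	0	0.01	10	1.0146	6.6647673	0.0006565	**	up
novel_mir_88	AAATTGGCTCTGTAAATTTCT	0	0.01	45	4.5656	8.8346607	5.40e-15	**	up
novel_mir_9	TCGAATCTGTATGAATTGCCT	39	3.6858	28	2.8408	-0.375681	0.2972265	ns	none
novel_mir_90	TGAACTGATCTTGATTTTGCAG	0	0.01	10	1.0146	6.6647673	0.0006565	**	up
novel_mir_92	TGCCAAGAAGCACATTCCTCC	0	0.01	14	1.4204	7.1501535	3.55e-05	**	up
novel_mir_94	TGTAGGGAGTAGAATGCAGCC	0	0.01	16	1.6233	7.3427858	8.26e-06	**	up
novel_mir_95	TTAGATGATCATCAACAAACA	0	0.01	61	6.1889	9.2735392	4.62e-20	**	up
novel_mir_97	TCTGGAAGCAATCAGGAGACT	0	0.01	10	1.0146	6.6647673	0.0006565	**	up
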