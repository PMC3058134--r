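subject_id	sample_id	sample_type	stage	load_percent	replicate_index	pool_id
SYN-P2	embryo01	embryo	day3	18.3649189909456	NA	NA
SYN-P2	embryo02	embryo	day3	0	NA	NA
SYN-P2	embryo03	embryo	day3	24.4629615467897	NA	NA
SYN-P2	embryo04	embryo	day3	88.2795956494314	NA	NA
SYN-P2	embryo05	embryo	day3	21.7019007963535	NA	NA
SYN-P2	embryo06	embryo	day3	32.9550554335032	NA	NA
SYN-P2	embryo07	embryo	day3	89.9879462587242	NA	NA
SYN-P2	embryo08	embryo	day3	53.4190420629699	NA	NA
SYN-P2	embryo09	embryo	day3	17.3695380866468	NA	NA
SYN-P2	embryo10	embryo	day3	88.8152177959429	NA	NA
SYN-P2	embryo11	embryo	day3	10.8715331069186	NA	NA
SYN-P2	embryo12	embryo	day3	47.1221183036996	NA	NA
SYN-P2	embryo13	embryo	day3	54.4181787155557	NA	NA
SYN-P2	embryo14	embryo	day3	22.1973483630303	NA	NA
SYN-P2	embryo15	embryo	day3	32.397460532713	NA	NA
SYN-P2	embryo16	embryo	day3	33.7200215502981	NA	NA
SYN-P2	embryo17	embryo	day3	62.5076175845299	NA	NA
SYN-P2	embryo18	embryo	day3	22.3923019405412	NA	NA
SYN-P2	embryo19	embryo	day3	62.1242103242723	NA	NA
SYN-P2	embryo20	embryo	day3	70.0601075387383	NA	NA
SYN-P2	embryo21	embryo	day3	9.59954372086524	NA	NA
SYN-P2	embryo22	embryo	day3	12.98617699815	NA	NA
SYN-P2	embryo23	embryo	day3	6.48509308862301	NA	NA
SYN-P2	embryo24	embryo	day3	12.1677118987844	NA	NA
SYN-P2	embryo25	embryo	day3	9.66688190303261	NA	NA
SYN-P2	embryo26	embryo	day3	16.7034539864718	NA	NA
SYN-P2	embryo27	embryo	day3	26.2896676653554	NA	NA
SYN-P2	embryo28	embryo	day3	0	NA	NA
SYN-P2	embryo29	embryo	day3	70.5946385289551	NA	NA
SYN-P2	embryo30	embryo	day3	21.2817752477114	NA	NA
SYN-P2	embryo31	embryo	day3	24.7575230376605	NA	NA
SYN-P2	embryo32	embryo	day3	56.151658825166	NA	NA
SYN-P2	embryo33	embryo	day3	29.3806547306929	NA	NA
SYN-P2	embryo34	embryo	day3	49.7934893815431	NA	NA
SYN-P2	embryo35	embryo	day3	10.4054531644869	NA	NA
SYN-P2	embryo01	blastomere	day3	19.3548339243987	1	NA
SYN-P2	embryo02	blastomere	day3	4.36212240757234	1	NA
SYN-P2	embryo03	blastomere	day3	21.9166572431297	1	NA
SYN-P2	embryo04	blastomere	day3	88.4557245362816	1	NA
SYN-P2	embryo05	blastomere	day3	19.9209616843091	1	NA
SYN-P2	embryo06	blastomere	day3	32.2038599956036	1	NA
SYN-P2	embryo07	blastomere	day3	90.0703072697793	1	NA
SYN-P2	embryo08	blastomere	day3	54.7574672491654	1	NA
SYN-P2	embryo09	blastomere	day3	21.0583713650125	1	NA
SYN-P2	embryo10	blastomere	day3	88.2367278758916	1	NA
SYN-P2	embryo11	blastomere	day3	9.28738943381326	1	NA
SYN-P2	embryo12	blastomere	day3	43.6330260993018	1	NA
SYN-P2	embryo13	blastomere	day3	52.9186050439515	1	NA
SYN-P2	embryo14	blastomere	day3	21.6676041662182	1	NA
SYN-P2	embryo15	blastomere	day3	31.5026490405408	1	NA
SYN-P2	embryo16	blastomere	day3	36.0812461903097	1	NA
SYN-P2	embryo17	blastomere	day3	62.9281290456959	1	NA
SYN-P2	embryo18	blastomere	day3	19.9700276889855	1	NA
SYN-P2	embryo19	blastomere	day3	60.4836200667386	1	NA
SYN-P2	embryo20	blastomere	day3	69.7942615477381	1	NA
SYN-P2	embryo21	blastomere	day3	8.77850103496233	1	NA
SYN-P2	embryo22	blastomere	day3	11.895218966556	1	NA
SYN-P2	embryo23	blastomere	day3	5.97064208203815	1	NA
SYN-P2	embryo24	blastomere	day3	10.5356249556016	1	NA
SYN-P2	embryo25	blastomere	day3	13.0762114784716	1	NA
SYN-P2	embryo26	blastomere	day3	17.3828916111209	1	NA
SYN-P2	embryo27	blastomere	day3	24.3350698641277	1	NA
SYN-P2	embryo28	blastomere	day3	0.0423961617371981	1	NA
SYN-P2	embryo29	blastomere	day3	70.6549806811995	1	NA
SYN-P2	embryo30	blastomere	day3	20.5043198469474	1	NA
SYN-P2	embryo31	blastomere	day3	24.4832780116488	1	NA
SYN-P2	embryo32	blastomere	day3	57.9834677018262	1	NA
SYN-P2	embryo33	blastomere	day3	29.3461230459892	1	NA
SYN-P2	embryo34	blastomere	day3	49.8303641421596	1	NA
SYN-P2	embryo35	blastomere	day3	9.20214708175634	1	NA
SYN-P2	embryo01	blastomere	day3	20.0758554081271	2	NA
SYN-P2	embryo02	blastomere	day3	2.97904523127462	2	NA
SYN-P2	embryo03	blastomere	day3	20.6688362486819	2	NA
SYN-P2	embryo04	blastomere	day3	86.1386293920438	2	NA
SYN-P2	embryo05	blastomere	day3	19.3447563523079	2	NA
SYN-P2	embryo06	blastomere	day3	33.2733265015121	2	NA
SYN-P2	embryo07	blastomere	day3	86.8607408287317	2	NA
SYN-P2	embryo08	blastomere	day3	54.9270679305184	2	NA
SYN-P2	embryo09	blastomere	day3	25.3671242710157	2	NA
SYN-P2	embryo10	blastomere	day3	89.0682082194359	2	NA
SYN-P2	embryo11	blastomere	day3	7.67491847699641	2	NA
SYN-P2	embryo12	blastomere	day3	42.4189078523667	2	NA
SYN-P2	embryo13	blastomere	day3	56.0654931110735	2	NA
SYN-P2	embryo14	blastomere	day3	23.7742700071904	2	NA
SYN-P2	embryo15	blastomere	day3	33.5354518005616	2	NA
SYN-P2	embryo16	blastomere	day3	34.1418927330343	2	NA
SYN-P2	embryo17	blastomere	day3	62.8566100641771	2	NA
SYN-P2	embryo18	blastomere	day3	20.6593863270475	2	NA
SYN-P2	embryo19	blastomere	day3	61.9251057825429	2	NA
SYN-P2	embryo20	blastomere	day3	68.6841382127739	2	NA
SYN-P2	embryo21	blastomere	day3	9.05594944691576	2	NA
SYN-P2	embryo22	blastomere	day3	10.6055424054445	2	NA
SYN-P2	embryo23	blastomere	day3	6.89235113600061	2	NA
SYN-P2	embryo24	blastomere	day3	13.063137756123	2	NA
SYN-P2	embryo25	blastomere	day3	9.47541920473811	2	NA
SYN-P2	embryo26	blastomere	day3	15.3395905189993	2	NA
SYN-P2	embryo27	blastomere	day3	25.2319304700364	2	NA
SYN-P2	embryo28	blastomere	day3	0	2	NA
SYN-P2	embryo29	blastomere	day3	72.0159047006689	2	NA
SYN-P2	embryo30	blastomere	day3	18.6212306074612	2	NA
SYN-P2	embryo31	blastomere	day3	24.7259321315849	2	NA
SYN-P2	embryo32	blastomere	day3	60.8305229886747	2	NA
SYN-P2	embryo33	blastomere	day3	28.2096074732283	2	NA
SYN-P2	embryo34	blastomere	day3	50.7532120150982	2	NA
SYN-P2	embryo35	blastomere	day3	8.84761683705234	2	NA
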