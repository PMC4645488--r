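family	gene_id	chromosome	start	end
1	GRMZM5G896901	1	65769722	65771244
1	GRMZM2G454718	5	55977976	55979514
2	GRMZM2G443525	1	164103203	164108542
2	GRMZM2G044724	3	85672960	85676903
3	GRMZM2G076474	2	113990307	113993559
3	GRMZM2G142680	10	94979016	94982685
4	GRMZM2G065692	2	134668301	134679003
4	LOC100383650	2	134763564	134769552
4	GRMZM2G003755	2	134763419	134769548
5	GRMZM2G074496	2	225896403	225899247
5	AC195587.4_FGP004	6	78774141	78783661
6	GRMZM2G070503	2	236854869	236856413
6	GRMZM2G026083	7	2515278	2517156
6	GRMZM2G026189	7	2525679	2527394
6	LOC103631898	7	2539874	2544540
6	GRMZM2G403407	7	2563208	2564699
6	LOC103631902	7	2569872	2585021
6	GRMZM2G060714	7	28599482	28602195
6	GRMZM5G827455	7	2582504	2583985
7	GRMZM2G094664	2	237541842	237545769
7	LOC103648313	2	237541778	237547469
8	GRMZM2G064015	3	132410799	132412650
8	GRMZM2G302279	3	132637536	132639351
9	GRMZM2G005347	4	203407679	203411878
9	GRMZM2G005452	4	203456994	203463296
9	GRMZM2G167049	4	203818715	203824772
10	GRMZM2G162098	5	55459467	55463724
10	GRMZM2G091672	5	55578326	55582323
10	GRMZM2G091696	5	55590775	55599910
10	GRMZM2G105428	5	55809843	55813411
11	GRMZM2G306727	6	7232528	7235241
11	GRMZM2G334584	6	8100151	8105044
12	LOC103630086	6	128972997	128982259
12	GRMZM2G397785	10	97377587	97383756
13	GRMZM2G169584	8	155079613	155081884
13	GRMZM2G169571	8	155119523	155121206
14	GRMZM2G180244	10	2052395	2058076
14	GRMZM2G180254	10	2127268	2133476
14	GRMZM2G004412	10	2987324	2996389
14	GRMZM5G819919	10	2842742	2846127
15	AC152495.1_FGP002	10	3283523	3287419
15	AC152495.1_FGP003	10	3299975	3307226
15	AC152495.1_FGP010	10	3372154	3376038
15	AC152495.1_FGP015	10	3404105	3405367
15	AC152495.1_FGP017	10	3441445	3444666
15	GRMZM5G879178	10	3445065	3449748
15	GRMZM2G069382	10	3571990	3590706
15	GRMZM2G083246	10	3645995	3648135
15	GRMZM2G143769	10	3687121	3688770
15	GRMZM2G443939	10	3700999	3705985
15	GRMZM2G349565	10	3767328	3769922
15	GRMZM2G003625	10	3849433	3854134
15	GRMZM2G061742	10	3907357	3911655
15	GRMZM2G005134	10	3983698	3989918
16	GRMZM2G319375	2	206507648	206508569
16	GRMZM2G394261	7	158297463	158301857
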