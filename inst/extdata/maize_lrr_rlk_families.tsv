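family	gene_id	chromosome	start	end
1	GRMZM2G371137	1	5803454	5808250
1	GRMZM2G172014	9	153777111	153781389
2	GRMZM2G009818	1	9800492	9804655
2	GRMZM2G438840	9	152523091	152526601
2	GRMZM2G168603	5	68680529	68684140
3	GRMZM2G153393	1	17640006	17655596
3	GRMZM2G330907	9	150263840	150275563
3	GRMZM2G004572	1	141080538	141086039
4	GRMZM2G038165	1	26120398	26128604
4	GRMZM2G069201	3	185481180	185489362
4	GRMZM2G089461	6	154565943	154575228
4	GRMZM2G174585	6	154839078	154847341
5	GRMZM2G043584	1	30258404	30262357
5	GRMZM2G141517	7	4082077	4086056
5	GRMZM2G072569	1	282595023	282599365
6	GRMZM5G886952	1	38791249	38799875
6	GRMZM2G479243	9	140610164	140617939
7	GRMZM2G084587	1	76878185	76889886
7	GRMZM2G122717	4	27843728	27845162
8	GRMZM2G093809	1	180006011	180009342
8	GRMZM2G080503	3	92276172	92279783
9	GRMZM2G461278	1	180366146	180370208
9	GRMZM2G147857	3	93326318	93329971
10	GRMZM2G428554	1	210641732	210645615
10	GRMZM2G011806	4	61742558	61747904
11	GRMZM2G001812	1	233516803	233520836
11	GRMZM2G112309	5	30237719	30241622
12	GRMZM2G137788	1	268802186	268806287
12	GRMZM2G158359	5	10425114	10429156
13	GRMZM2G114276	2	16005190	16009431
13	GRMZM2G016477	10	136139046	136143214
14	GRMZM2G021619	2	36708164	36710640
14	GRMZM2G167280	10	126603529	126608907
15	GRMZM2G073928	2	161907176	161910550
15	GRMZM2G432642	7	18436556	18440330
16	GRMZM2G163724	2	164310419	164313687
16	GRMZM2G072868	7	50383762	50386524
17	GRMZM2G002569	2	182995589	182999190
17	GRMZM2G084248	7	117574984	117578965
18	AC233861.1_FG001	2	189738061	189741584
18	GRMZM2G149051	7	130969891	130973647
18	GRMZM2G039431	4	197994710	197998218
18	GRMZM2G131609	6	129696721	129700755
18	GRMZM2G463493	8	17060563	17064940
19	GRMZM2G172429	2	201545881	201550118
19	GRMZM2G313643	7	150075579	150080212
20	GRMZM2G162781	2	213192905	213197565
20	GRMZM2G081857	7	167142415	167147144
21	GRMZM2G169681	2	219686483	219692413
21	GRMZM2G068398	4	10223589	10229102
22	GRMZM2G349875	2	221419815	221427366
22	GRMZM2G104384	4	17311139	17323011
23	GRMZM2G012861	3	2763089	2767869
23	GRMZM2G127687	8	26863212	26867537
24	GRMZM2G010693	3	12429859	12434725
24	GRMZM2G067675	8	17304016	17309182
25	GRMZM2G463574	3	16573593	16577181
25	GRMZM2G421669	8	14848451	14851761
26	GRMZM2G138338	3	147442361	147446195
26	GRMZM2G059117	8	157002878	157006630
27	GRMZM2G447447	3	161622655	161626810
27	GRMZM2G306771	5	123289050	123293128
28	GRMZM2G145753	3	184727722	184731545
28	GRMZM2G128315	6	154358844	154362599
29	GRMZM2G465771	3	185367968	185371929
29	AC218972.3_FG004	8	170198252	170201068
29	AC214817.3_FG004	6	154514150	154517066
30	GRMZM2G078926	3	209624891	209634088
30	GRMZM2G059497	8	149851364	149863364
31	GRMZM2G339540	3	224241290	224255475
31	GRMZM2G050548	8	141765271	141771284
32	GRMZM2G438007	4	65769675	65773352
32	GRMZM2G092604	7	79119386	79123848
33	GRMZM2G150024	4	124660672	124667062
33	GRMZM2G115420	5	176261637	176267226
33	GRMZM2G384439	10	71477986	71484046
33	GRMZM5G870959	10	121772419	121777860
34	GRMZM2G071396	4	138248437	138252721
34	GRMZM2G702599	4	139022453	139031123
34	GRMZM2G039665	4	139156285	139159606
35	GRMZM2G150930	4	165794972	165797318
35	GRMZM2G171114	6	103870389	103873917
36	GRMZM2G100234	4	226544149	226547671
36	GRMZM2G176206	5	151922862	151926238
37	GRMZM2G451007	4	237861330	237864849
37	GRMZM2G177570	5	51462007	51465569
37	GRMZM2G474777	6	88899974	88903683
37	GRMZM2G104425	5	81113414	81119465
38	GRMZM2G322348	4	240249146	240253001
38	GRMZM2G123314	8	14843475	14846908
39	GRMZM2G126161	5	42533252	42537728
39	GRMZM2G100858	6	91599104	91604620
40	GRMZM2G463904	5	211800909	211813877
40	GRMZM5G809695	6	108369697	108377055
40	GRMZM2G082855	9	24074354	24081173
41	GRMZM2G125081	6	5162305	5165886
41	GRMZM2G045981	9	146683625	146687407
42	GRMZM2G162531	6	97773823	97791863
42	GRMZM2G071573	9	98256956	98262572
43	GRMZM2G449817	6	104839663	104842894
43	GRMZM2G350918	9	74480747	74484663
44	GRMZM2G349665	6	116081434	116084931
44	GRMZM2G145720	9	35179613	35185362
44	GRMZM2G019317	5	204644182	204648555
45	GRMZM2G149201	6	130782221	130784726
45	GRMZM2G151738	8	89697764	89700024
46	GRMZM2G046729	9	146340642	146344213
46	AC233893.1_FG006	9	146407378	146411588
47	GRMZM2G009770	9	152025490	152029185
47	GRMZM5G839644	10	6940302	6943942
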