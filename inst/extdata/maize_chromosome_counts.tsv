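chromosome	nbs_lrr	lrr_rlk
1	11	31
2	22	22
3	12	24
4	28	32
5	10	21
6	10	22
7	18	23
8	6	18
9	2	20
10	32	13
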