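chain	subdomain	start	end
K1	E1	1	60
K1	V1	61	153
K1	H1	154	180
K1	1A	181	215
K1	L1	216	226
K1	1B	227	328
K1	L12	329	345
K1	2A	346	364
K1	L2	365	372
K1	2B	373	486
K1	H2	487	497
K1	V2	498	607
K1	E2	608	644
K10	E1	1	30
K10	V1	31	137
K10	H1	138	149
K10	1A	150	184
K10	L1	185	195
K10	1B	196	296
K10	L12	297	313
K10	2A	314	332
K10	L2	333	340
K10	2B	341	452
K10	H2	453	460
K10	V2	461	558
K10	E2	559	584
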