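z_abs	gamma1	w1	p_mc	mc_se	p_quad
1.0	0.01	0.2500000000	0.0069938	0.00002635315306	0.006965366252
2.0	0.01	0.2500000000	0.0026606	0.00001628963231	0.002638319442
2.5	0.01	0.2500000000	0.0011482	0.00001070925598	0.001151257892
1.0	0.10	0.2500000000	0.0524397	0.00007049097663	0.052391357635
2.0	0.10	0.2500000000	0.0137616	0.00003684049181	0.013735075363
2.5	0.10	0.2500000000	0.0048893	0.00002205763982	0.004905455097
1.0	0.50	0.2500000000	0.1877587	0.00012349306482	0.187649553473
2.0	0.50	0.2500000000	0.0335259	0.00005692267916	0.033491762143
2.5	0.50	0.2500000000	0.0100078	0.00003147641012	0.010031888836
1.0	0.01	0.3333333333	0.0078833	0.00002796632543	0.007895857799
2.0	0.01	0.3333333333	0.0034488	0.00001853889365	0.003452164691
2.5	0.01	0.3333333333	0.0016055	0.00001266065705	0.001595439828
1.0	0.10	0.3333333333	0.0592796	0.00007467632089	0.059258453183
2.0	0.10	0.3333333333	0.0169435	0.00004081227488	0.016868396677
2.5	0.10	0.3333333333	0.0061478	0.00002471842340	0.006108813431
1.0	0.50	0.3333333333	0.1988971	0.00012622877786	0.198879463833
2.0	0.50	0.3333333333	0.0365180	0.00005931646962	0.036555523926
2.5	0.50	0.3333333333	0.0108828	0.00003280909122	0.010889778307
1.0	0.01	0.5000000000	0.0092420	0.00003025985036	0.009229431683
2.0	0.01	0.5000000000	0.0051873	0.00002271649603	0.005220905581
2.5	0.01	0.5000000000	0.0026243	0.00001617842097	0.002667949753
1.0	0.10	0.5000000000	0.0725882	0.00008204824996	0.072743182638
2.0	0.10	0.5000000000	0.0233783	0.00004778258583	0.023416675392
2.5	0.10	0.5000000000	0.0084814	0.00002899907904	0.008465406707
1.0	0.50	0.5000000000	0.2239557	0.00013183305520	0.224187741832
2.0	0.50	0.5000000000	0.0414539	0.00006303608028	0.041524603781
2.5	0.50	0.5000000000	0.0119693	0.00003438900385	0.011978691264
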