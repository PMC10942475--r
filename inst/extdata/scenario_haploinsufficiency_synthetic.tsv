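enrichment	log2fc
1.031	-1.0105
1.037	-0.9742
1.081	-1.3
1.089	-1.3
1.117	-1.1865
1.124	-0.855
1.126	-0.5655
1.138	-0.7397
1.158	-1.0677
1.188	-0.5377
1.275	-1.1172
1.286	-1.0749
1.391	-0.8931
1.448	-1.1252
1.519	-0.7632
1.541	-1.219
1.545	-1.143
1.55	-0.9435
1.569	-1.1125
1.583	-0.9109
1.617	-1.1603
1.667	-0.8769
1.679	-0.7323
1.774	-1.3
1.795	-0.7486
1.877	-0.7359
1.888	-0.8257
1.893	-0.5591
1.909	-0.9452
1.996	-0.6007
2.003	-1.2962
2.026	-0.8388
2.049	-0.8659
2.137	-0.5616
2.176	-0.6431
2.193	-0.993
2.329	-0.7807
2.499	-0.6018
2.595	-0.8097
2.642	-0.8965
2.655	-0.8241
2.725	-0.8025
2.788	-0.7231
2.843	-0.6339
2.846	-0.9034
2.869	-0.7634
2.926	-0.5631
2.94	-0.8191
2.946	-0.7222
3.048	-0.8363
3.175	-0.633
3.178	-0.6469
3.26	-0.5262
3.295	-0.8704
3.327	-0.7675
3.361	-0.6894
3.461	-0.4845
3.498	-0.8099
3.546	-0.6125
3.605	-0.9227
3.688	-0.616
3.706	-0.5199
3.706	-0.5839
3.719	-0.5951
3.731	-0.5201
3.943	-0.9175
4.273	-0.7367
4.307	-0.5062
4.437	-0.5532
4.443	-0.4842
4.507	-0.4212
4.511	-0.4541
4.594	-0.5933
4.844	-0.5953
4.913	-0.7485
5.043	-0.7089
5.071	-0.5526
5.114	-0.6601
5.132	-0.6516
5.366	-0.5426
5.405	-0.5598
5.445	-0.7963
5.59	-0.5428
5.606	-0.4004
5.664	-0.4824
5.686	-0.491
5.693	-0.5309
5.872	-0.4743
5.95	-0.5635
5.976	-0.4986
5.997	-0.58
6.068	-0.5212
6.097	-0.538
6.136	-0.5197
6.152	-0.6963
6.156	-0.5254
6.251	-0.4716
6.295	-0.6363
6.319	-0.3468
6.33	-0.5438
6.415	-0.4713
6.502	-0.5282
6.533	-0.4731
6.555	-0.4167
6.612	-0.3343
6.655	-0.3539
6.662	-0.4345
6.819	-0.4907
7.144	-0.2776
7.171	-0.3427
7.186	-0.4873
7.247	-0.4464
7.277	-0.4192
7.329	-0.5365
7.71	-0.2849
7.764	-0.4805
7.8	-0.2889
7.898	-0.4213
7.922	-0.3708
7.93	-0.3713
8.073	-0.4446
8.194	-0.3791
8.264	-0.3896
8.561	-0.319
8.653	-0.2493
8.732	-0.4085
8.89	-0.4119
8.918	-0.3178
9.064	-0.2564
9.8	-0.433
9.813	-0.2483
9.914	-0.2926
9.931	-0.223
10.041	-0.2498
10.061	-0.269
10.223	-0.2172
10.343	-0.2937
10.349	-0.2822
10.397	-0.2534
10.537	-0.3053
10.585	-0.2802
10.831	-0.2662
11.039	-0.3202
11.048	-0.227
11.069	-0.2
11.172	-0.3002
11.245	-0.1958
11.388	-0.2585
11.41	-0.1889
11.46	-0.2587
11.602	-0.2065
11.641	-0.2221
11.755	-0.1555
12.128	-0.1908
12.146	-0.1901
12.167	-0.2167
12.452	-0.2213
12.528	-0.2262
12.577	-0.1769
12.811	-0.1687
13.788	-0.2215
14.265	-0.154
14.303	-0.1639
14.335	-0.0957
14.474	-0.1452
14.49	-0.164
14.59	-0.1721
14.893	-0.2047
14.944	-0.1574
15.227	-0.1618
16.186	-0.1584
16.336	-0.1623
16.907	-0.1011
17.122	-0.1483
17.29	-0.1257
17.575	-0.1195
18.351	-0.1329
18.394	-0.1175
19.077	-0.1123
19.119	-0.0743
19.209	-0.1225
19.946	-0.1089
20.076	-0.1053
20.529	-0.0919
20.952	-0.1366
21.043	-0.1012
21.28	-0.0661
21.755	-0.1012
22.035	-0.0962
22.737	-0.0811
23.103	-0.0857
26.768	-0.0421
28.039	-0.0627
32.614	-0.0509
34.179	-0.0511
34.534	-0.0655
37.403	-0.0475
38.817	-0.0387
39.496	-0.0483
45.918	-0.0612
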