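enrichment	log2fc
1.017	-0.1404
1.019	-0.1504
1.02	-0.1496
1.137	-0.1317
1.145	-0.1444
1.194	-0.1439
1.225	-0.216
1.27	-0.1882
1.327	-0.1981
1.404	-0.1562
1.414	-0.1471
1.471	-0.1449
1.484	-0.1695
1.504	-0.1638
1.519	-0.1759
1.574	-0.1083
1.655	-0.2181
1.73	-0.182
1.872	-0.2184
1.891	-0.2496
1.936	-0.175
1.954	-0.2027
1.979	-0.2774
2.037	-0.3711
2.067	-0.2383
2.095	-0.3015
2.109	-0.2043
2.128	-0.4145
2.176	-0.3091
2.183	-0.287
2.331	-0.4284
2.441	-0.2749
2.704	-0.4461
2.72	-0.4999
2.72	-0.5516
2.73	-0.3454
2.745	-0.3611
2.787	-0.448
2.804	-0.4388
2.859	-0.3714
2.942	-0.5124
2.973	-0.423
2.986	-0.4165
3.085	-0.2984
3.096	-0.2836
3.204	-0.6958
3.265	-0.2527
3.447	-0.4338
3.518	-0.5082
3.571	-0.3377
3.601	-0.6295
3.611	-0.7845
3.727	-0.4291
3.813	-0.7794
3.849	-0.7122
3.891	-0.5261
3.997	-0.6619
4	-0.3992
4.027	-0.6523
4.03	-0.6797
4.042	-0.7355
4.069	-0.6042
4.146	-0.7017
4.239	-0.8639
4.256	-0.4422
4.295	-1.1074
4.313	-0.56
4.315	-0.6869
4.339	-0.993
4.349	-0.6217
4.424	-0.7297
4.528	-0.6371
4.539	-0.5431
4.715	-0.8474
4.853	-0.948
4.933	-0.8191
4.995	-0.9144
5.125	-0.7279
5.189	-0.7327
5.286	-0.7498
5.3	-0.9119
5.332	-0.6923
5.434	-1.2094
5.441	-1.4181
5.517	-0.6824
5.532	-0.6535
5.532	-0.5367
5.719	-0.8658
5.767	-1.2051
5.822	-1.5035
5.863	-1.0834
5.88	-1.3933
5.898	-1.0222
5.977	-1.2047
6.022	-1.0038
6.037	-1.0245
6.042	-1.3111
6.15	-0.8538
6.156	-1.5886
6.188	-1.2472
6.206	-1.6894
6.487	-1.1392
6.532	-1.13
6.557	-1.3156
6.609	-1.6174
6.832	-1.7266
6.833	-1.2545
6.953	-1.0906
6.961	-1.372
7.028	-1.3623
7.046	-1.063
7.058	-1.662
7.097	-1.5479
7.159	-0.8183
7.183	-1.6748
7.313	-1.2631
7.339	-0.9081
7.845	-1.7331
7.894	-1.5702
7.905	-1.1419
8.114	-1.961
8.178	-0.9887
8.238	-1.9914
8.265	-1.4908
8.571	-1.8512
8.717	-1.8345
8.825	-1.7953
8.959	-1.179
9.037	-1.1876
9.041	-1.2014
9.246	-0.9798
9.374	-1.6439
9.544	-1.6935
9.759	-1.5009
9.77	-1.838
9.913	-2.6392
10.326	-1.7364
10.47	-1.1517
10.482	-2.4771
10.512	-1.7909
10.553	-2.0238
10.556	-1.8114
10.704	-1.6378
10.715	-2.14
10.866	-1.2361
10.938	-1.7686
11.187	-1.3689
11.2	-1.6084
11.213	-1.9461
11.444	-2.4038
11.716	-1.3025
11.735	-1.7566
12.148	-2.0826
12.305	-2.1317
12.383	-2.7403
12.6	-1.6501
12.635	-3.029
12.988	-2.0589
13.054	-1.3216
13.281	-1.3266
13.29	-2.9782
13.304	-2.1773
13.308	-2.1797
13.463	-2.7111
13.479	-2.0848
13.515	-1.8565
13.598	-3.3257
13.661	-1.8111
14.092	-2.1517
14.171	-1.8788
14.603	-2.0988
14.925	-1.9235
15.123	-2.573
16.034	-1.6368
16.487	-3.5166
16.958	-1.7395
17.066	-1.7499
17.29	-2.1782
17.418	-2.7935
17.524	-2.5118
17.525	-1.9594
17.646	-2.6898
17.846	-2.8547
19.24	-2.6052
20.043	-3.2365
20.392	-2.4792
21.401	-1.303
22.061	-3.0669
22.865	-2.1612
23.73	-2.6779
23.761	-2.0327
24.336	-3.4864
25.786	-2.2583
25.851	-2.6607
26.093	-2.8752
28.37	-2.5368
28.611	-2.0455
34.219	-2.5403
41.114	-4.8054
53.731	-2.5818
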