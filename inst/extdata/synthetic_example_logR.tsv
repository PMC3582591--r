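chrom	pos	tumor_a	tumor_b
1	1000000	-0.0894	0.0056
1	1050000	-0.3477	-0.0713
1	1100000	0.0358	0.1705
1	1150000	0.3795	0.1027
1	1200000	-0.4544	0.2036
1	1250000	0.1961	-0.2043
1	1300000	-0.2798	-0.1123
1	1350000	0.365	-0.2025
1	1400000	0.2763	-0.6042
1	1450000	-0.1678	0.0665
1	1500000	-0.0524	0.2481
1	1550000	-0.0138	0.1343
1	1600000	-0.0758	-0.266
1	1650000	0.5164	-0.1701
1	1700000	0.026	-0.3578
1	1750000	-0.1426	0.2463
1	1800000	0.1276	-0.0669
1	1850000	0.0403	-0.1935
1	1900000	-0.014	0.1759
1	1950000	-0.0185	-0.0507
1	2000000	0.0898	-0.3036
1	2050000	-0.2129	-0.0048
1	2100000	-0.2325	0.0053
1	2150000	0.3297	0.0327
1	2200000	-0.4124	0.082
1	2250000	0.0025	-0.1255
1	2300000	-0.2175	0.1274
1	2350000	0.0541	-0.2404
1	2400000	0.2017	0.2693
1	2450000	-0.4149	-0.1198
1	2500000	0.1794	0.0884
1	2550000	-0.01	0.1227
1	2600000	-0.2691	-0.0598
1	2650000	-0.3862	-0.3201
1	2700000	0.1419	-0.0679
1	2750000	-0.0316	-0.1163
1	2800000	0.0433	-0.0781
1	2850000	0.1635	0.1691
1	2900000	0.3454	0.1369
1	2950000	-0.0208	0.0475
1	3000000	0.7886	-0.1421
1	3050000	1.1857	0.5227
1	3100000	0.7214	-0.3253
1	3150000	0.6685	-0.3215
1	3200000	0.7939	0.0681
1	3250000	1.3891	0.5456
1	3300000	0.7335	-0.0654
1	3350000	0.9827	-0.2514
1	3400000	0.6643	-0.0863
1	3450000	0.6652	0.5098
1	3500000	0.8334	-0.4628
1	3550000	1.1726	-0.1015
1	3600000	0.8062	-0.054
1	3650000	1.0686	0.1496
1	3700000	0.6084	0.1337
1	3750000	0.8199	-0.0911
1	3800000	0.7447	-0.3856
1	3850000	0.8261	0.3764
1	3900000	1.148	-0.2499
1	3950000	0.8785	-0.2936
1	4000000	0.9345	-0.6569
1	4050000	0.9509	-0.6156
1	4100000	0.7771	-0.9442
1	4150000	0.6142	-0.5127
1	4200000	0.8338	-0.5227
1	4250000	0.0257	-0.605
1	4300000	0.2036	-0.526
1	4350000	-0.0511	-0.8773
1	4400000	-0.0605	-0.7257
1	4450000	0.323	-0.4807
1	4500000	-0.1547	-0.5964
1	4550000	0.0848	-0.6204
1	4600000	-0.1168	-0.4867
1	4650000	0.083	-0.7899
1	4700000	-0.3091	-0.5748
1	4750000	-0.1037	-0.8638
1	4800000	-0.056	-0.7527
1	4850000	0.2015	-0.6691
1	4900000	-0.0939	-0.5863
1	4950000	0.0596	-1.232
1	5000000	-0.0836	-0.4727
1	5050000	-0.1701	-0.6156
1	5100000	0.1378	-0.43
1	5150000	-0.092	-0.4792
1	5200000	0.8089	-0.5706
1	5250000	0.0886	-0.6649
1	5300000	-0.0302	-0.5693
1	5350000	0.0911	-0.7131
1	5400000	-0.008	-0.5709
1	5450000	0.0912	-0.6271
1	5500000	-0.0817	-0.5313
1	5550000	-0.4273	-0.8353
1	5600000	0.0314	-0.7783
1	5650000	0.132	-0.619
1	5700000	-0.1964	-0.9214
1	5750000	-0.2227	-0.7767
1	5800000	-0.0875	-0.6412
1	5850000	-0.1032	-0.3414
1	5900000	0.2514	-0.5372
1	5950000	0.0268	-0.964
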