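# Theoretical anomalous dispersion corrections for Zn (Z=30)
# Cromer-Liberman calculation, tabulated via the gemmi library.
# energy_eV f_prime f_doubleprime
1000.0 -21.9442 2.2611
1001.9 -22.7070 2.2552
1003.8 -23.5927 2.2494
1005.7 -24.6365 2.2436
1007.6 -25.8899 2.2379
1009.5 -27.4316 2.2321
1011.4 -29.3900 2.2264
1013.3 -31.9951 2.2207
1015.1 -35.7244 2.2151
1017.0 -41.8581 2.2094
1018.9 -57.0585 2.2038
1020.8 -51.0806 42.5923
1022.7 -36.6171 39.9964
1024.6 -29.5633 37.5979
1026.5 -25.1123 35.3801
1028.4 -22.0792 33.3276
1030.3 -19.9847 31.4268
1032.2 -18.6001 29.6651
1034.1 -17.8240 28.0311
1036.0 -17.6527 26.5143
1037.9 -18.2138 25.1054
1039.8 -19.9554 23.7957
1041.7 -24.9394 22.5773
1043.5 -26.6932 41.5633
1045.4 -17.0911 39.2436
1047.3 -12.7002 37.0898
1049.2 -9.8527 35.0884
1051.1 -7.8049 33.2273
1053.0 -6.2609 31.4954
1054.9 -5.0678 29.8826
1056.8 -4.1342 28.3798
1058.7 -3.4001 26.9783
1060.6 -2.8234 25.6704
1062.5 -2.3734 24.4492
1064.4 -2.0266 23.3080
1066.3 -1.7651 22.2409
1068.2 -1.5744 21.2425
1070.1 -10.3808 20.3434
1072.0 -10.0930 19.8529
1075.7 -9.6241 18.9597
1077.6 -9.4339 18.5528
1081.4 -9.1228 17.8091
1087.1 -8.7887 16.8448
1092.8 -8.5665 16.0305
1094.7 -12.8954 15.8425
1102.2 -12.3324 15.6546
1109.8 -11.8354 15.4704
1119.3 -11.2916 15.2452
1128.8 -10.8214 15.0253
1138.2 -10.4165 14.8107
1147.7 -10.0732 14.6011
1157.2 -9.7927 14.3963
1164.7 -9.6199 14.2360
1172.3 -9.5070 14.0786
1178.0 -9.4808 13.9624
1183.7 -9.5455 13.8478
1187.5 -9.6966 13.7723
1189.3 -9.8478 13.7348
1191.2 -10.1279 13.6975
1193.1 -11.0083 13.6603
1195.0 -10.2985 15.4534
1196.9 -9.7458 15.4149
1198.8 -9.4237 15.3765
1200.7 -9.1851 15.3383
1202.6 -8.9903 15.3002
1206.4 -8.6738 15.2247
1210.2 -8.4141 15.1498
1215.9 -8.0851 15.0388
1227.2 -7.5485 14.8211
1242.4 -6.9702 14.5397
1251.8 -6.6581 14.3687
1276.4 -5.9770 13.9478
1299.2 -5.4389 13.5784
1323.8 -4.9374 13.1975
1325.7 -5.0166 13.1691
1354.1 -4.5127 12.7762
1356.0 -4.5332 12.7508
1403.3 -3.8347 12.1544
1441.2 -3.3677 11.7074
1480.9 -2.9462 11.2644
1518.8 -2.5983 10.8657
1568.0 -2.1975 10.3772
1626.7 -1.7946 9.8342
1681.6 -1.4970 9.3637
1744.1 -1.2156 8.8688
1810.4 -0.9705 8.3862
1882.4 -0.7543 7.9060
1961.9 -0.5633 7.4222
2086.8 -0.3263 6.7468
2189.1 -0.1999 6.2589
2312.2 -0.0937 5.7402
2442.8 -0.0193 5.2581
2671.9 0.0396 4.5499
2923.8 0.0427 3.9275
3156.7 0.0130 3.4583
3406.6 -0.0396 3.0435
3637.6 -0.0991 2.7245
3887.5 -0.1685 2.4338
4368.5 -0.3106 1.9934
4849.4 -0.4485 1.6631
5330.3 -0.5883 1.4096
5813.2 -0.7312 1.2098
6294.1 -0.8761 1.0511
6775.1 -1.0288 0.9222
7256.0 -1.1972 0.8160
7738.8 -1.3946 0.7271
8219.8 -1.6426 0.6525
8700.7 -1.9939 0.5889
8969.6 -2.2850 0.5573
9181.6 -2.6192 0.5339
9266.8 -2.8021 0.5249
9342.6 -3.0050 0.5171
9407.0 -3.2236 0.5106
9461.9 -3.4637 0.5052
9509.2 -3.7364 0.5006
9547.1 -4.0304 0.4969
9577.4 -4.3534 0.4940
9602.0 -4.7257 0.4917
9619.0 -5.0983 0.4901
9626.6 -5.3204 0.4894
9632.3 -5.5252 0.4889
9638.0 -5.7802 0.4883
9641.7 -5.9929 0.4880
9645.5 -6.2596 0.4876
9649.3 -6.6167 0.4873
9651.2 -6.8533 0.4871
9653.1 -7.1576 0.4869
9655.0 -7.5844 0.4868
9656.9 -8.3025 0.4866
9658.8 -11.4444 0.4864
9660.7 -8.4355 3.8955
9662.6 -7.6473 3.8940
9664.5 -7.1939 3.8924
9666.4 -6.8739 3.8908
9668.3 -6.6263 3.8892
9672.0 -6.2532 3.8861
9675.8 -5.9744 3.8829
9679.6 -5.7516 3.8798
9689.1 -5.3344 3.8720
9702.3 -4.9285 3.8611
9717.5 -4.5926 3.8488
9736.4 -4.2761 3.8335
9759.1 -3.9837 3.8153
9798.9 -3.6006 3.7839
9848.1 -3.2524 3.7458
9908.7 -2.9295 3.7001
9978.8 -2.6415 3.6488
10058.3 -2.3834 3.5925
10126.5 -2.2133 3.5458
10132.2 -2.2376 3.5419
10134.0 -2.6164 3.5407
10135.9 -2.1665 3.5396
10137.8 -2.1937 3.5386
10145.4 -2.1942 3.5345
10366.9 -1.7671 3.4165
10626.3 -1.4080 3.2858
10851.7 -1.1713 3.1782
11107.3 -0.9570 3.0624
11588.2 -0.6548 2.8609
12071.1 -0.4363 2.6779
12499.0 -0.2919 2.5299
12540.6 -0.2895 2.5161
12552.0 -0.3217 2.5124
12553.9 -0.3570 2.5118
12555.8 -0.5805 2.5112
12557.7 -0.0726 2.5105
12559.6 -0.1913 2.5099
12561.5 -0.2189 2.5093
12578.5 -0.2492 2.5037
13032.9 -0.1411 2.3601
13513.9 -0.0429 2.2212
13994.8 0.0349 2.0943
14477.6 0.0973 1.9775
14958.6 0.1473 1.8707
15439.5 0.1875 1.7723
15920.5 0.2199 1.6814
16403.3 0.2462 1.5970
16884.2 0.2671 1.5190
17365.2 0.2837 1.4466
17846.1 0.2969 1.3792
18327.0 0.3070 1.3164
18809.9 0.3145 1.2575
19290.8 0.3090 1.2026
19307.9 0.2889 1.2007
19313.5 0.2462 1.2001
19315.4 0.1863 1.1999
19317.3 -0.3540 1.1997
19319.2 0.5482 1.1995
19321.1 0.4196 1.1993
19324.9 0.3681 1.1989
19343.8 0.3355 1.1968
19771.8 0.3272 1.1510
20252.7 0.3291 1.1026
20735.5 0.3301 1.0570
21216.5 0.3300 1.0144
21697.4 0.3292 0.9742
22178.3 0.3276 0.9364
22659.3 0.3255 0.9007
23142.1 0.3227 0.8669
23623.1 0.3196 0.8351
24104.0 0.3161 0.8049
24584.9 0.3123 0.7764
25067.8 0.3082 0.7492
25548.7 0.3040 0.7235
26029.6 0.2996 0.6991
26510.6 0.2950 0.6759
26991.5 0.2904 0.6537
27474.4 0.2856 0.6325
27955.3 0.2809 0.6124
28436.2 0.2760 0.5932
28917.2 0.2712 0.5749
29400.0 0.2663 0.5574
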