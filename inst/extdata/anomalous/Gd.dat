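# Theoretical anomalous dispersion corrections for Gd (Z=64)
# Cromer-Liberman calculation, tabulated via the gemmi library.
# energy_eV f_prime f_doubleprime
1000.0 -33.4680 8.1152
1037.9 -34.9361 7.8587
1068.2 -36.6326 7.6629
1092.8 -38.6506 7.5093
1102.2 -39.7087 7.4513
1111.7 -41.0118 7.3941
1119.3 -42.3022 7.3488
1126.9 -43.9057 7.3040
1134.4 -45.9591 7.2596
1140.1 -47.9244 7.2266
1145.8 -50.4158 7.1938
1149.6 -52.4805 7.1721
1153.4 -54.9851 7.1505
1157.2 -58.0693 7.1289
1159.1 -59.9042 7.1182
1160.9 -61.9793 7.1074
1162.8 -64.3428 7.0967
1164.7 -67.0572 7.0860
1166.6 -70.2043 7.0754
1168.5 -73.8940 7.0648
1170.4 -78.2782 7.0542
1172.3 -83.5739 7.0436
1174.2 -90.1056 7.0330
1176.1 -98.3877 7.0225
1178.0 -109.3039 7.0120
1179.9 -124.5679 7.0015
1181.8 -148.2321 6.9911
1183.7 -194.8159 6.9807
1185.6 -292.2567 215.7955
1187.5 -155.2875 196.5945
1189.3 -108.8358 179.3506
1191.2 -81.8219 163.8481
1193.1 -64.1255 149.8968
1195.0 -52.0459 137.3285
1196.9 -43.7788 125.9945
1198.8 -38.3122 115.7633
1200.7 -35.0415 106.5181
1202.6 -33.6087 98.1556
1204.5 -33.8337 90.5839
1206.4 -35.6967 83.7215
1208.3 -39.3679 77.4957
1210.2 -45.3177 71.8420
1212.1 -54.6366 66.7028
1214.0 -70.1543 62.0267
1215.9 -103.0165 57.7680
1217.7 -141.1495 188.3124
1219.6 -67.8391 172.8022
1221.5 -39.2754 158.7826
1223.4 -22.1977 146.0976
1225.3 -10.7766 134.6089
1227.2 -2.7724 124.1932
1229.1 2.9486 114.7412
1231.0 7.0517 106.1553
1232.9 9.9652 98.3486
1234.8 11.9819 91.2436
1236.7 13.3114 84.7709
1238.6 14.1082 78.8688
1240.5 14.4891 73.4818
1242.4 14.5445 68.5604
1244.3 -14.0789 64.4758
1246.1 -13.5681 61.3869
1248.0 -13.2344 58.5623
1249.9 -13.0430 55.9770
1253.7 -12.9811 51.4357
1257.5 -13.2168 47.6081
1261.3 -13.6389 44.3689
1263.2 -13.8955 42.9374
1267.0 -14.4650 40.3963
1270.8 -15.0768 38.2236
1276.4 -16.0170 35.5250
1278.3 -34.8097 35.1976
1295.4 -32.5937 34.5260
1316.2 -30.4115 33.7321
1338.9 -28.4901 32.8980
1363.5 -26.8002 32.0301
1391.9 -25.2347 31.0723
1422.2 -23.9298 30.0989
1452.5 -22.9590 29.1721
1480.9 -22.3694 28.3428
1511.2 -22.2482 27.4978
1522.6 -22.4935 27.1909
1530.2 -22.8835 26.9892
1535.8 -23.4683 26.8394
1539.6 -24.2509 26.7403
1541.5 -25.1329 26.6916
1543.4 -27.1706 26.6438
1545.3 -25.9238 31.1391
1547.2 -24.5686 31.0770
1549.1 -23.8369 31.0152
1551.0 -23.3223 30.9536
1554.8 -22.5862 30.8314
1560.5 -21.8199 30.6501
1569.9 -20.9285 30.3534
1581.3 -20.1521 30.0058
1607.8 -18.9662 29.2399
1619.2 -18.5693 28.9254
1621.1 -18.7704 28.8780
1649.5 -18.0589 28.2300
1670.3 -17.8524 27.7682
1681.6 -18.1081 27.5210
1685.4 -18.5006 27.4393
1687.3 -19.0908 27.3986
1689.2 -19.0742 29.2413
1691.1 -18.3464 29.1948
1693.0 -17.9829 29.1485
1702.5 -17.0650 28.9191
1721.4 -16.0956 28.4713
1747.9 -15.1842 27.8677
1770.6 -14.5785 27.3706
1772.5 -14.6614 27.3321
1823.7 -13.6571 26.3569
1854.0 -13.3101 25.8035
1867.2 -13.3077 25.5668
1874.8 -13.4694 25.4330
1878.6 -13.7692 25.3665
1880.5 -14.4362 25.3333
1882.4 -13.8362 26.4760
1884.2 -13.5028 26.4421
1888.0 -13.1566 26.3744
1901.3 -12.5353 26.1395
1925.9 -11.8368 25.7122
1961.9 -11.0804 25.1075
2052.8 -9.6608 23.6886
2164.5 -8.3781 22.1059
2287.6 -7.3170 20.5396
2442.8 -6.3200 18.7913
2658.7 -5.4022 16.7109
2923.8 -4.7352 14.6107
3160.4 -4.3777 13.0528
3406.6 -4.1888 11.6878
3887.5 -4.1521 9.5924
4368.5 -4.3628 8.0351
4849.4 -4.7276 6.8434
5330.3 -5.2180 5.9080
5813.2 -5.8891 5.1555
6294.1 -6.8349 4.5460
6561.1 -7.5891 4.2551
6775.1 -8.4340 4.0424
6936.0 -9.3724 3.8930
7055.3 -10.4544 3.7878
7138.6 -11.7358 3.7170
7168.9 -12.4837 3.6917
7191.6 -13.2844 3.6730
7206.8 -14.0506 3.6605
7220.0 -15.0544 3.6497
7229.5 -16.2336 3.6420
7235.2 -17.4576 3.6374
7237.1 -18.0857 3.6359
7238.9 -18.9682 3.6344
7240.8 -20.4630 3.6328
7242.7 -28.0294 3.6313
7244.6 -20.6314 10.6049
7246.5 -19.0475 10.5986
7248.4 -18.1294 10.5923
7252.2 -16.9768 10.5797
7256.0 -16.2187 10.5672
7263.6 -15.2008 10.5423
7271.1 -14.5025 10.5175
7282.5 -13.7461 10.4806
7297.6 -13.0229 10.4318
7335.5 -11.8594 10.3122
7388.5 -10.8927 10.1502
7462.4 -10.0823 9.9345
7555.2 -9.4980 9.6790
7598.7 -9.3328 9.5647
7600.6 -9.4697 9.5604
7738.8 -9.3134 9.2756
7844.9 -9.7537 9.0655
7878.9 -10.1821 8.9994
7903.6 -10.8033 8.9521
7916.8 -11.4999 8.9267
7924.4 -12.3722 8.9123
7926.3 -12.7897 8.9087
7928.2 -13.4924 8.9051
7930.1 -16.3812 8.9015
7932.0 -13.6470 12.2897
7933.8 -12.8495 12.2847
7935.7 -12.3913 12.2796
7943.3 -11.4352 12.2595
7954.7 -10.7259 12.2293
7969.8 -10.1619 12.1893
8007.7 -9.3424 12.0903
8062.6 -8.6561 11.9493
8136.4 -8.0882 11.7641
8219.8 -7.7182 11.5611
8320.1 -7.6226 11.3246
8322.0 -7.7525 11.3202
8350.4 -7.9959 11.2561
8367.5 -8.4986 11.2179
8373.1 -9.0185 11.2052
8375.0 -9.4670 11.2009
8376.9 -10.1601 12.9406
8378.8 -9.2019 12.9362
8382.6 -8.6453 12.9274
8386.4 -8.3593 12.9186
8401.5 -7.7734 12.8834
8428.0 -7.2544 12.8221
8530.3 -6.2367 12.5898
8700.7 -5.2544 12.2161
8787.8 -4.9721 12.0315
8789.7 -4.7573 12.0275
9181.6 -3.6052 11.2328
9662.6 -2.6146 10.3584
10145.4 -1.9382 9.5826
10626.3 -1.4537 8.8949
10866.8 -1.2752 8.5791
10887.6 -1.4208 8.5526
10889.5 0.8738 8.5502
10891.4 -1.0934 8.5478
10895.2 -1.1881 8.5430
11107.3 -1.0954 8.2804
11588.2 -0.8305 7.7293
12071.1 -0.6293 7.2312
12552.0 -0.4776 6.7828
13032.9 -0.3629 6.3760
13513.9 -0.2770 6.0058
13994.8 -0.2135 5.6677
14477.6 -0.1676 5.3570
14958.6 -0.1322 5.0721
15439.5 -0.1127 4.8099
15844.7 -0.0972 4.6049
15858.0 -0.0605 4.5985
15859.9 0.0943 4.5975
15861.8 -0.1773 4.5966
15920.5 -0.1009 4.5680
16403.3 -0.0978 4.3431
16730.9 -0.1269 4.2001
16747.9 -0.2238 4.1928
16749.8 -0.2980 4.1920
16751.7 -0.5878 4.1912
16753.6 1.0092 4.1904
16755.5 0.1644 4.1896
16761.2 -0.0169 4.1872
16884.2 -0.0924 4.1355
17365.2 -0.1048 3.9426
17846.1 -0.1178 3.7633
18327.0 -0.1337 3.5963
18809.9 -0.1522 3.4399
19290.8 -0.1726 3.2943
19771.8 -0.1948 3.1580
20252.7 -0.2182 3.0301
20735.5 -0.2429 2.9097
21216.5 -0.2683 2.7969
21697.4 -0.2943 2.6906
22178.3 -0.3209 2.5905
22659.3 -0.3478 2.4960
23142.1 -0.3751 2.4063
23623.1 -0.4025 2.3218
24104.0 -0.4300 2.2418
24584.9 -0.4576 2.1659
25067.8 -0.4854 2.0936
25548.7 -0.5130 2.0252
26029.6 -0.5406 1.9602
26510.6 -0.5682 1.8983
26991.5 -0.5959 1.8392
27474.4 -0.6238 1.7826
27955.3 -0.6515 1.7289
28436.2 -0.6791 1.6776
28917.2 -0.7067 1.6286
29400.0 -0.7344 1.5816
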