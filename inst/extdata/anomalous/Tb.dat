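# Theoretical anomalous dispersion corrections for Tb (Z=65)
# Cromer-Liberman calculation, tabulated via the gemmi library.
# energy_eV f_prime f_doubleprime
1000.0 -32.2366 8.6148
1051.1 -33.5985 8.2473
1073.8 -34.4148 8.0924
1094.7 -35.3337 7.9546
1113.6 -36.3698 7.8327
1128.8 -37.3979 7.7374
1142.0 -38.4917 7.6555
1155.3 -39.8959 7.5745
1166.6 -41.4506 7.5062
1176.1 -43.1229 7.4501
1183.7 -44.8271 7.4057
1191.2 -47.0110 7.3617
1196.9 -49.1018 7.3290
1202.6 -51.7531 7.2965
1206.4 -53.9508 7.2750
1208.3 -55.2170 7.2643
1212.1 -58.1751 7.2430
1214.0 -59.9154 7.2323
1215.9 -61.8721 7.2217
1217.7 -64.0865 7.2111
1219.6 -66.6116 7.2005
1221.5 -69.5158 7.1900
1223.4 -72.8897 7.1795
1225.3 -76.8562 7.1690
1227.2 -81.5872 7.1585
1229.1 -87.3324 7.1481
1231.0 -94.4735 7.1377
1232.9 -103.6334 7.1273
1234.8 -115.9317 7.1169
1236.7 -133.6962 7.1066
1238.6 -163.2107 7.0963
1240.5 -237.9818 7.0860
1242.4 -205.3470 202.4200
1244.3 -133.7084 185.6471
1246.1 -98.5453 170.4759
1248.0 -76.4663 156.7406
1249.9 -61.4525 144.2939
1251.8 -50.9514 133.0046
1253.7 -43.6247 122.7557
1255.6 -38.6893 113.4430
1257.5 -35.6633 104.9733
1259.4 -34.2549 97.2634
1261.3 -34.3118 90.2389
1263.2 -35.8072 83.8333
1265.1 -38.8579 77.9868
1267.0 -43.7931 72.6461
1268.9 -51.3402 67.7631
1270.8 -63.1847 63.2948
1272.7 -84.3096 59.2024
1274.6 -149.1950 55.4511
1276.4 -96.9597 180.7724
1278.3 -55.1509 166.7937
1280.2 -33.1439 154.0831
1282.1 -18.9471 142.5152
1284.0 -9.0782 131.9777
1285.9 -1.9795 122.3704
1287.8 3.2012 113.6034
1289.7 6.9884 105.5962
1291.6 9.7308 98.2766
1293.5 11.6727 91.5796
1295.4 12.9922 85.4472
1297.3 13.8225 79.8268
1299.2 14.2658 74.6713
1301.1 14.4020 69.9383
1303.0 -14.1242 65.9540
1304.8 -13.5718 62.9431
1306.7 -13.1901 60.1772
1308.6 -12.9478 57.6341
1310.5 -12.8192 55.2936
1312.4 -12.7831 53.1376
1314.3 -12.8220 51.1499
1318.1 -13.0699 47.6211
1321.9 -13.4748 44.6048
1323.8 -13.7164 43.2620
1327.6 -14.2491 40.8617
1331.4 -14.8204 38.7909
1337.0 -15.6995 36.1912
1338.9 -34.6709 35.8513
1352.2 -32.9448 35.3140
1367.3 -31.2698 34.7155
1382.5 -29.8359 34.1333
1399.5 -28.4471 33.4968
1418.5 -27.1262 32.8117
1437.4 -25.9958 32.1489
1458.2 -24.9368 31.4442
1480.9 -23.9724 30.7034
1511.2 -22.9677 29.7584
1541.5 -22.2920 28.8591
1568.0 -22.0585 28.1074
1587.0 -22.2855 27.5895
1596.4 -22.7029 27.3362
1602.1 -23.2284 27.1859
1605.9 -23.8842 27.0865
1607.8 -24.4531 27.0370
1609.7 -25.5233 26.9877
1611.6 -27.9741 31.5041
1613.5 -24.9742 31.4419
1615.4 -24.1670 31.3819
1617.3 -23.5557 31.3222
1621.1 -22.7338 31.2035
1626.7 -21.9153 31.0275
1634.3 -21.1478 30.7961
1643.8 -20.4323 30.5122
1657.0 -19.6652 30.1245
1689.2 -18.4684 29.2449
1691.1 -18.6503 29.1968
1719.5 -17.9163 28.5614
1742.2 -17.5944 28.0676
1753.6 -17.6225 27.8254
1761.2 -17.8756 27.6656
1765.0 -18.2953 27.5862
1766.9 -18.9524 27.5466
1768.7 -18.7781 29.4132
1770.6 -18.0958 29.3676
1772.5 -17.7416 29.3221
1776.3 -17.2896 29.2315
1783.9 -16.7163 29.0521
1800.9 -15.8878 28.6567
1827.4 -14.9990 28.0636
1854.0 -14.3215 27.4953
1855.8 -14.4192 27.4578
1918.3 -13.3084 26.3064
1946.7 -13.0850 25.8069
1961.9 -13.3020 25.5462
1965.7 -13.6556 25.4817
1967.6 -14.9266 26.6339
1969.5 -13.5664 26.6007
1973.2 -13.0937 26.5346
1980.8 -12.6478 26.4031
2011.1 -11.7189 25.8875
2062.2 -10.7076 25.0535
2139.9 -9.5702 23.8814
2228.9 -8.5471 22.6367
2329.2 -7.6303 21.3475
2442.8 -6.8205 20.0171
2656.8 -5.7209 17.8288
2923.8 -4.8953 15.5784
3156.7 -4.4649 13.9458
3406.6 -4.1991 12.4684
3639.5 -4.0843 11.3011
3887.5 -4.0675 10.2365
4368.5 -4.2122 8.5754
4849.4 -4.5211 7.3042
5330.3 -4.9551 6.3071
5813.2 -5.5192 5.5048
6294.1 -6.2860 4.8544
6775.1 -7.4294 4.3173
7055.3 -8.4939 4.0460
7165.1 -9.0992 3.9468
7256.0 -9.7609 3.8675
7333.6 -10.5402 3.8018
7394.2 -11.4277 3.7517
7439.7 -12.4611 3.7149
7456.7 -13.0259 3.7012
7471.8 -13.6927 3.6891
7481.3 -14.2473 3.6816
7490.8 -14.9937 3.6741
7498.4 -15.8574 3.6681
7504.0 -16.8465 3.6636
7507.8 -17.8967 3.6606
7509.7 -18.7017 3.6591
7511.6 -19.9857 3.6576
7513.5 -23.4425 3.6561
7515.4 -21.1999 10.6124
7517.3 -19.2935 10.6061
7519.2 -18.2808 10.5999
7521.1 -17.5864 10.5937
7524.9 -16.6292 10.5813
7530.5 -15.6883 10.5627
7536.2 -15.0271 10.5442
7551.4 -13.8623 10.4953
7564.6 -13.1833 10.4530
7579.8 -12.6002 10.4053
7619.5 -11.5608 10.2825
7672.6 -10.6965 10.1246
7738.8 -10.0078 9.9361
7807.0 -9.5466 9.7519
7882.7 -9.2253 9.5582
7884.6 -9.3599 9.5538
7969.8 -9.1770 9.3836
8049.3 -9.1760 9.2287
8109.9 -9.3262 9.1131
8157.3 -9.6027 9.0243
8193.3 -10.0099 8.9576
8219.8 -10.5912 8.9089
8233.0 -11.1423 8.8847
8242.5 -11.8975 8.8675
8246.3 -12.4775 8.8606
8248.2 -12.9556 8.8571
8250.1 -13.8328 8.8537
8252.0 -15.4877 12.3317
8253.8 -13.4199 12.3260
8255.7 -12.7341 12.3203
8259.5 -11.9998 12.3088
8267.1 -11.2305 12.2861
8278.5 -10.5860 12.2522
8291.7 -10.1044 12.2131
8335.3 -9.1883 12.0872
8380.7 -8.6285 11.9600
8439.4 -8.1478 11.8021
8505.7 -7.7934 11.6317
8573.8 -7.5943 11.4648
8657.2 -7.6964 11.2718
8685.6 -8.0531 11.2117
8695.0 -8.3111 11.1918
8700.7 -8.6025 11.1799
8704.5 -8.9890 11.1719
8706.4 -9.4081 11.1679
8708.3 -10.3895 12.9049
8710.2 -9.2337 12.9004
8712.1 -8.8767 12.8959
8719.6 -8.2583 12.8781
8740.5 -7.5975 12.8293
8776.4 -7.0349 12.7466
8837.0 -6.4535 12.6110
8926.0 -5.8580 12.4211
9181.6 -4.6567 11.9027
9403.2 -3.9479 11.4631
9662.6 -3.3079 10.9797
10145.4 -2.4412 10.1599
10626.3 -1.8390 9.4340
11107.3 -1.3983 8.7852
11588.2 -1.0687 8.2028
12071.1 -0.8198 7.6761
12552.0 -0.6308 7.2018
13032.9 -0.4864 6.7714
13513.9 -0.3762 6.3796
13994.8 -0.2929 6.0217
14477.6 -0.2304 5.6927
14958.6 -0.1851 5.3918
15439.5 -0.1494 5.1141
15920.5 -0.1290 4.8578
16403.3 -0.1175 4.6200
16884.2 -0.1100 4.4000
17365.2 -0.1120 4.1957
17846.1 -0.1171 4.0055
18327.0 -0.1280 3.8282
18809.9 -0.1422 3.6622
19290.8 -0.1590 3.5076
19771.8 -0.1779 3.3629
20252.7 -0.1985 3.2272
20735.5 -0.2206 3.0992
21216.5 -0.2438 2.9794
21697.4 -0.2678 2.8666
22178.3 -0.2926 2.7602
22659.3 -0.3179 2.6597
23142.1 -0.3438 2.5645
23623.1 -0.3699 2.4747
24104.0 -0.3962 2.3896
24584.9 -0.4227 2.3090
25067.8 -0.4494 2.2321
25548.7 -0.4760 2.1594
26029.6 -0.5027 2.0903
26510.6 -0.5294 2.0245
26991.5 -0.5562 1.9617
27474.4 -0.5832 1.9014
27955.3 -0.6100 1.8443
28436.2 -0.6368 1.7897
28917.2 -0.6636 1.7375
29400.0 -0.6904 1.6875
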