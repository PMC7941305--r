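# Theoretical anomalous dispersion corrections for Br (Z=35)
# Cromer-Liberman calculation, tabulated via the gemmi library.
# energy_eV f_prime f_doubleprime
1000.0 -8.0369 4.5418
1043.5 -8.2102 4.2845
1090.9 -8.4420 4.0304
1136.3 -8.7057 3.8086
1178.0 -8.9884 3.6222
1215.9 -9.2860 3.4651
1251.8 -9.6125 3.3258
1297.3 -10.0832 3.1622
1323.8 -10.4082 3.0720
1352.2 -10.8312 2.9796
1376.8 -11.2612 2.9031
1399.5 -11.7290 2.8352
1420.3 -12.2409 2.7753
1439.3 -12.8050 2.7226
1454.4 -13.3545 2.6815
1467.7 -13.9402 2.6464
1475.3 -14.3360 2.6267
1480.9 -14.6713 2.6121
1486.6 -15.0477 2.5976
1492.3 -15.4750 2.5832
1498.0 -15.9670 2.5690
1501.8 -16.3400 2.5595
1505.6 -16.7575 2.5502
1509.3 -17.2294 2.5409
1513.1 -17.7688 2.5316
1516.9 -18.3935 2.5224
1520.7 -19.1282 2.5132
1522.6 -19.5475 2.5087
1524.5 -20.0090 2.5041
1526.4 -20.5201 2.4996
1528.3 -21.0903 2.4951
1530.2 -21.7318 2.4906
1532.1 -22.4602 2.4861
1534.0 -23.2972 2.4816
1535.8 -24.2724 2.4772
1537.7 -25.4289 2.4727
1539.6 -26.8318 2.4683
1541.5 -28.5870 2.4638
1543.4 -30.8836 2.4594
1545.3 -34.1111 2.4550
1547.2 -39.3065 2.4506
1549.1 -51.7468 2.4463
1551.0 -48.1442 36.2147
1552.9 -36.1469 34.8354
1554.8 -30.1568 33.5233
1556.7 -26.1785 32.2749
1558.6 -23.2519 31.0866
1560.5 -20.9856 29.9552
1562.4 -19.1789 28.8777
1564.3 -17.7143 27.8511
1566.1 -16.5171 26.8727
1568.0 -15.5370 25.9400
1569.9 -14.7389 25.0505
1571.8 -14.0978 24.2021
1573.7 -13.5963 23.3925
1575.6 -13.2226 22.6197
1577.5 -12.9702 21.8819
1579.4 -12.8372 21.1773
1581.3 -12.8272 20.5041
1583.2 -12.9509 19.8607
1585.1 -13.2293 19.2457
1587.0 -13.7001 18.6577
1588.9 -14.4334 18.0952
1590.8 -15.5703 17.5571
1592.7 -17.4547 17.0421
1594.5 -21.3629 16.5491
1596.4 -27.6521 32.8833
1598.3 -17.9080 31.7682
1600.2 -14.2128 30.7035
1602.1 -11.8601 29.6867
1604.0 -10.1445 28.7152
1605.9 -8.8116 27.7867
1607.8 -7.7381 26.8992
1609.7 -6.8540 26.0505
1611.6 -6.1150 25.2388
1613.5 -5.4912 24.4622
1615.4 -4.9612 23.7189
1617.3 -4.5090 23.0073
1619.2 -4.1225 22.3260
1621.1 -3.7920 21.6733
1622.9 -3.5097 21.0480
1624.8 -3.2694 20.4488
1626.7 -10.6223 19.9389
1630.5 -10.0886 19.2829
1632.4 -9.8583 18.9748
1636.2 -9.4586 18.3949
1640.0 -9.1267 17.8599
1645.7 -8.7292 17.1325
1651.4 -8.4253 16.4844
1658.9 -8.1278 15.7259
1666.5 -7.9207 15.0694
1674.1 -7.7792 14.4980
1676.0 -11.4488 14.4452
1689.2 -10.9503 14.2686
1702.5 -10.5268 14.0953
1717.6 -10.1251 13.9009
1730.9 -9.8450 13.7342
1744.1 -9.6412 13.5704
1755.5 -9.5501 13.4324
1765.0 -9.5765 13.3189
1770.6 -9.6834 13.2515
1774.4 -9.8392 13.2069
1776.3 -9.9695 13.1846
1778.2 -10.1722 13.1625
1780.1 -10.5509 13.1403
1782.0 -15.0413 13.1183
1783.9 -10.4631 15.0211
1785.8 -9.9935 14.9970
1787.7 -9.7013 14.9729
1789.6 -9.4820 14.9489
1793.4 -9.1494 14.9011
1799.0 -8.7786 14.8299
1804.7 -8.4840 14.7593
1810.4 -8.2327 14.6893
1823.7 -7.7438 14.5281
1840.7 -7.2306 14.3252
1859.6 -6.7500 14.1056
1869.1 -6.5345 13.9979
1871.0 -6.5224 13.9770
1908.9 -5.7814 13.5747
1933.5 -5.3705 13.3228
1961.9 -4.9483 13.0411
2011.1 -4.3189 12.5745
2058.4 -3.8209 12.1526
2113.4 -3.3220 11.6912
2168.3 -2.8923 11.2563
2228.9 -2.4877 10.8045
2295.1 -2.1125 10.3411
2365.2 -1.7755 9.8828
2442.8 -1.4644 9.4098
2547.0 -1.1253 8.8275
2660.6 -0.8347 8.2524
2785.5 -0.5876 7.6829
2923.8 -0.3811 7.1196
3156.7 -0.1392 6.3001
3406.6 0.0050 5.5666
3639.5 0.0846 4.9939
3887.5 0.1094 4.4769
4120.4 0.1062 4.0630
4368.5 0.0843 3.6835
4601.4 0.0523 3.3747
4849.4 0.0100 3.0875
5330.3 -0.0852 2.6276
5813.2 -0.1887 2.2636
6294.1 -0.2938 1.9724
6714.5 -0.3853 1.7622
6716.4 -0.4065 1.7614
6718.2 -0.3847 1.7605
6775.1 -0.3970 1.7347
7256.0 -0.5003 1.5378
7738.8 -0.6033 1.3725
8219.8 -0.7069 1.2333
8700.7 -0.8117 1.1147
9181.6 -0.9185 1.0116
9662.6 -1.0313 0.9219
10145.4 -1.1543 0.8435
10626.3 -1.2911 0.7752
11107.3 -1.4493 0.7151
11588.2 -1.6413 0.6618
12071.1 -1.8919 0.6142
12328.6 -2.0658 0.5909
12552.0 -2.2545 0.5718
12822.8 -2.5635 0.5499
13032.9 -2.9199 0.5338
13174.9 -3.2856 0.5233
13231.7 -3.4878 0.5192
13281.0 -3.7088 0.5156
13322.6 -3.9483 0.5127
13358.6 -4.2190 0.5101
13387.0 -4.5042 0.5082
13411.6 -4.8436 0.5065
13426.8 -5.1302 0.5054
13440.0 -5.4724 0.5045
13449.5 -5.8146 0.5038
13457.1 -6.2054 0.5033
13460.9 -6.4752 0.5031
13462.8 -6.6420 0.5029
13464.6 -6.8408 0.5028
13466.5 -7.0866 0.5027
13468.4 -7.4088 0.5025
13470.3 -7.8767 0.5024
13472.2 -8.7428 0.5023
13474.1 -10.1088 3.8232
13476.0 -8.2861 3.8220
13477.9 -7.6503 3.8209
13479.8 -7.2549 3.8197
13481.7 -6.9671 3.8186
13483.6 -6.7405 3.8175
13487.4 -6.3943 3.8152
13493.0 -6.0224 3.8118
13496.8 -5.8306 3.8095
13502.5 -5.5946 3.8061
13513.9 -5.2358 3.7994
13525.2 -4.9658 3.7926
13538.5 -4.7165 3.7848
13553.6 -4.4866 3.7759
13570.7 -4.2742 3.7659
13612.3 -3.8787 3.7418
13663.5 -3.5283 3.7127
13725.9 -3.2083 3.6778
13801.7 -2.9115 3.6364
13890.7 -2.6393 3.5892
13994.8 -2.3867 3.5357
14134.9 -2.1181 3.4665
14136.8 -2.1181 3.4656
14138.7 -2.1644 3.4648
14297.8 -1.9231 3.4040
14477.6 -1.7012 3.3371
14703.0 -1.4750 3.2561
14958.6 -1.2665 3.1677
15439.5 -0.9646 3.0108
15920.5 -0.7390 2.8653
16403.3 -0.5627 2.7296
16884.2 -0.4222 2.6037
17365.2 -0.3077 2.4863
17846.1 -0.2101 2.3760
18327.0 -0.1315 2.2727
18809.9 -0.0652 2.1757
19290.8 -0.0095 2.0850
19771.8 0.0377 1.9999
20252.7 0.0780 1.9200
20735.5 0.1124 1.8444
21216.5 0.1418 1.7734
21697.4 0.1668 1.7065
22178.3 0.1882 1.6432
22659.3 0.2065 1.5834
23142.1 0.2221 1.5265
23623.1 0.2353 1.4729
24104.0 0.2464 1.4219
24584.9 0.2557 1.3736
25067.8 0.2635 1.3275
25548.7 0.2699 1.2838
26029.6 0.2751 1.2422
26510.6 0.2792 1.2025
26991.5 0.2852 1.1647
27474.4 0.2873 1.1282
27955.3 0.2887 1.0935
28436.2 0.2894 1.0604
28917.2 0.2895 1.0288
29400.0 0.2891 0.9985
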