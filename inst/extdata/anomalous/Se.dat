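# Theoretical anomalous dispersion corrections for Se (Z=34)
# Cromer-Liberman calculation, tabulated via the gemmi library.
# energy_eV f_prime f_doubleprime
1000.0 -8.6076 3.9974
1064.4 -9.0099 3.6689
1066.3 -8.9672 3.6598
1070.1 -8.9951 3.6416
1117.4 -9.3815 3.4264
1159.1 -9.7896 3.2538
1193.1 -10.1855 3.1229
1225.3 -10.6270 3.0071
1253.7 -11.0902 2.9106
1280.2 -11.6087 2.8250
1301.1 -12.0981 2.7606
1320.0 -12.6325 2.7041
1337.0 -13.2187 2.6548
1352.2 -13.8641 2.6122
1359.8 -14.2495 2.5913
1365.4 -14.5750 2.5758
1371.1 -14.9395 2.5605
1376.8 -15.3523 2.5453
1382.5 -15.8259 2.5303
1386.3 -16.1840 2.5203
1390.1 -16.5839 2.5104
1393.8 -17.0346 2.5006
1397.6 -17.5482 2.4909
1401.4 -18.1409 2.4812
1405.2 -18.8351 2.4715
1407.1 -19.2298 2.4667
1409.0 -19.6629 2.4619
1410.9 -20.1411 2.4572
1412.8 -20.6724 2.4524
1414.7 -21.2673 2.4477
1416.6 -21.9392 2.4430
1418.5 -22.7059 2.4383
1420.3 -23.5915 2.4336
1422.2 -24.6300 2.4289
1424.1 -25.8708 2.4242
1426.0 -27.3906 2.4196
1427.9 -29.3163 2.4149
1429.8 -31.8815 2.4103
1431.7 -35.5942 2.4057
1433.6 -41.9546 2.4011
1435.5 -63.3206 2.3966
1437.4 -44.3403 37.1475
1439.3 -34.4272 35.5933
1441.2 -28.8997 34.1219
1443.1 -25.1240 32.7283
1445.0 -22.3254 31.4080
1446.9 -20.1628 30.1567
1448.7 -18.4543 28.9702
1450.6 -17.0909 27.8448
1452.5 -16.0029 26.7770
1454.4 -15.1437 25.7634
1456.3 -14.4818 24.8010
1458.2 -13.9969 23.8868
1460.1 -13.6779 23.0180
1462.0 -13.5221 22.1922
1463.9 -13.5368 21.4069
1465.8 -13.7426 20.6599
1467.7 -14.1818 19.9490
1469.6 -14.9381 19.2724
1471.5 -16.1912 18.6280
1473.4 -18.4191 18.0141
1475.3 -23.8695 17.4292
1477.2 -23.4991 34.1374
1479.0 -16.6162 32.8603
1480.9 -13.2505 31.6463
1482.8 -11.0025 30.4919
1484.7 -9.3342 29.3938
1486.6 -8.0299 28.3489
1488.5 -6.9789 27.3542
1490.4 -6.1160 26.4070
1492.3 -5.3988 25.5048
1494.2 -4.7981 24.6450
1496.1 -4.2927 23.8255
1498.0 -3.8667 23.0441
1499.9 -3.5075 22.2988
1501.8 -3.2054 21.5876
1503.7 -2.9522 20.9088
1505.6 -2.7408 20.2607
1507.4 -10.3717 19.7694
1511.2 -9.8675 19.0793
1515.0 -9.4574 18.4482
1518.8 -9.1219 17.8700
1524.5 -8.7277 17.0906
1530.2 -8.4332 16.4030
1535.8 -8.2134 15.7941
1541.5 -8.0501 15.2531
1547.2 -7.9304 14.7705
1549.1 -11.7534 14.6367
1558.6 -11.3403 14.4983
1568.0 -10.9743 14.3618
1577.5 -10.6502 14.2273
1588.9 -10.3126 14.0683
1600.2 -10.0294 13.9120
1609.7 -9.8374 13.7837
1619.2 -9.6925 13.6572
1626.7 -9.6207 13.5573
1634.3 -9.6075 13.4585
1640.0 -9.6623 13.3850
1643.8 -9.7557 13.3364
1647.6 -9.9424 13.2881
1649.5 -10.1098 13.2640
1651.4 -10.3993 13.2400
1653.2 -11.1767 13.2160
1655.1 -10.7451 15.1069
1657.0 -10.1314 15.0810
1658.9 -9.7963 15.0552
1660.8 -9.5554 15.0294
1662.7 -9.3627 15.0037
1666.5 -9.0560 14.9526
1672.2 -8.7001 14.8764
1681.6 -8.2401 14.7509
1694.9 -7.7318 14.5783
1710.0 -7.2533 14.3851
1727.1 -6.7938 14.1730
1753.6 -6.2105 13.8597
1776.3 -5.7611 13.6023
1802.8 -5.2987 13.3113
1831.2 -4.8613 13.0102
1865.3 -4.3992 12.6629
1897.5 -4.0334 12.3511
1961.9 -3.3876 11.7640
2009.2 -2.9839 11.3597
2060.3 -2.6067 10.9463
2113.4 -2.2686 10.5413
2172.1 -1.9435 10.1184
2232.6 -1.6583 9.7079
2298.9 -1.3921 9.2871
2442.8 -0.9410 8.4634
2552.6 -0.6853 7.9069
2671.9 -0.4714 7.3627
2795.0 -0.3037 6.8583
2923.8 -0.1721 6.3842
3156.7 -0.0067 5.6402
3406.6 0.0804 4.9779
3637.6 0.1049 4.4658
3887.5 0.0996 3.9980
4120.4 0.0757 3.6266
4368.5 0.0372 3.2864
4849.4 -0.0584 2.7524
5330.3 -0.1664 2.3408
5813.2 -0.2784 2.0153
6294.1 -0.3878 1.7550
6775.1 -0.4976 1.5423
7256.0 -0.6063 1.3666
7738.8 -0.7169 1.2192
8219.8 -0.8286 1.0952
8700.7 -0.9442 0.9896
9181.6 -1.0663 0.8979
9662.6 -1.1999 0.8181
10145.4 -1.3526 0.7484
10626.3 -1.5336 0.6877
11107.3 -1.7624 0.6342
11588.2 -2.0807 0.5868
11855.2 -2.3324 0.5629
12071.1 -2.6134 0.5445
12243.4 -2.9334 0.5306
12377.8 -3.3043 0.5200
12430.8 -3.5069 0.5160
12478.2 -3.7355 0.5124
12517.9 -3.9832 0.5094
12552.0 -4.2632 0.5069
12584.2 -4.6313 0.5045
12597.4 -4.8346 0.5035
12608.8 -5.0494 0.5027
12618.3 -5.2715 0.5020
12627.7 -5.5561 0.5013
12635.3 -5.8592 0.5008
12641.0 -6.1643 0.5003
12644.8 -6.4325 0.5001
12646.7 -6.5978 0.4999
12648.6 -6.7943 0.4998
12650.5 -7.0364 0.4997
12652.4 -7.3514 0.4995
12654.2 -7.8029 0.4994
12656.1 -8.6081 0.4992
12658.0 -10.7234 3.8440
12659.9 -8.3575 3.8427
12661.8 -7.6768 3.8415
12663.7 -7.2637 3.8403
12665.6 -6.9659 3.8390
12667.5 -6.7328 3.8378
12669.4 -6.5412 3.8366
12673.2 -6.2369 3.8341
12677.0 -5.9994 3.8316
12682.6 -5.7186 3.8279
12694.0 -5.3096 3.8206
12709.2 -4.9277 3.8108
12730.0 -4.5532 3.7975
12754.6 -4.2281 3.7818
12784.9 -3.9244 3.7628
12820.9 -3.6445 3.7405
12862.5 -3.3875 3.7150
12911.8 -3.1429 3.6854
12968.6 -2.9129 3.6519
13032.9 -2.6980 3.6148
13146.5 -2.3961 3.5513
13279.1 -2.1233 3.4805
13281.0 -2.1824 3.4796
13513.9 -1.8174 3.3852
13737.3 -1.5560 3.2982
13994.8 -1.3175 3.2020
14477.6 -0.9823 3.0327
14958.6 -0.7386 2.8771
15439.5 -0.5517 2.7330
15920.5 -0.4041 2.5995
16403.3 -0.2845 2.4750
16884.2 -0.1840 2.3588
17365.2 -0.1039 2.2505
17846.1 -0.0372 2.1496
18327.0 0.0186 2.0552
18809.9 0.0658 1.9666
19290.8 0.1054 1.8839
19771.8 0.1389 1.8064
20252.7 0.1672 1.7334
20735.5 0.1913 1.6646
21216.5 0.2116 1.6000
21697.4 0.2287 1.5390
22178.3 0.2431 1.4814
22659.3 0.2551 1.4270
23142.1 0.2651 1.3753
23623.1 0.2733 1.3265
24104.0 0.2800 1.2803
24584.9 0.2853 1.2363
25067.8 0.2895 1.1945
25548.7 0.2929 1.1548
26029.6 0.2950 1.1170
26510.6 0.2963 1.0811
26991.5 0.2973 1.0467
27474.4 0.2978 1.0136
27955.3 0.2974 0.9822
28436.2 0.2965 0.9523
28917.2 0.2952 0.9237
29400.0 0.2934 0.8963
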