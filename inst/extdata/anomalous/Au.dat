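# Theoretical anomalous dispersion corrections for Au (Z=79)
# Cromer-Liberman calculation, tabulated via the gemmi library.
# energy_eV f_prime f_doubleprime
1000.0 -27.0781 20.8033
1094.7 -26.1388 19.1522
1204.5 -25.4892 17.4951
1335.1 -25.1586 15.8152
1337.0 -25.0074 15.7924
1409.0 -24.9133 14.9589
1480.9 -25.0603 14.1827
1622.9 -25.5592 12.8307
1749.8 -26.6508 11.7880
1867.2 -28.2315 10.9464
1961.9 -30.2128 10.3393
2014.9 -31.8624 10.0237
2056.6 -33.7096 9.7868
2088.7 -35.7844 9.6101
2102.0 -36.9277 9.5389
2115.2 -38.3383 9.4686
2126.6 -39.8509 9.4090
2136.1 -41.4166 9.3598
2145.5 -43.3786 9.3110
2153.1 -45.3521 9.2723
2160.7 -47.8414 9.2338
2166.4 -50.1860 9.2051
2172.1 -53.1128 9.1766
2175.8 -55.5081 9.1577
2179.6 -58.3882 9.1388
2183.4 -61.9190 9.1200
2185.3 -64.0136 9.1106
2187.2 -66.3868 9.1012
2189.1 -69.1034 9.0919
2191.0 -72.2519 9.0825
2192.9 -75.9587 9.0732
2194.8 -80.4110 9.0639
2196.7 -85.9048 9.0546
2198.6 -92.9479 9.0453
2200.5 -102.5263 9.0360
2202.3 -116.9901 9.0268
2204.2 -144.9708 9.0175
2206.1 -192.0720 124.5686
2208.0 -125.4153 119.8499
2209.9 -100.6602 115.3506
2211.8 -85.0811 111.0595
2213.7 -73.8122 106.9661
2215.6 -65.1052 103.0602
2217.5 -58.1183 99.3325
2219.4 -52.3757 95.7739
2221.3 -47.5799 92.3760
2223.2 -43.5308 89.1307
2225.1 -40.0870 86.0306
2227.0 -37.1444 83.0683
2228.9 -34.6239 80.2372
2230.7 -32.4640 77.5308
2232.6 -30.6159 74.9429
2234.5 -29.0403 72.4679
2236.4 -27.7053 70.1003
2240.2 -25.6561 65.6668
2242.1 -24.9022 63.5913
2245.9 -23.8606 59.7008
2249.7 -23.3699 56.1310
2251.6 -23.3124 54.4570
2255.4 -23.5513 51.3139
2259.2 -24.2539 48.4233
2261.0 -24.7830 47.0656
2264.8 -26.2240 44.5122
2268.6 -28.2472 42.1588
2270.5 -29.5205 41.0516
2272.4 -31.0041 39.9879
2274.3 -32.7379 38.9659
2276.2 -34.7769 37.9837
2278.1 -37.2008 37.0395
2280.0 -40.1283 36.1316
2281.9 -43.7468 35.2586
2283.8 -48.3763 34.4189
2285.7 -54.6304 33.6109
2287.6 -63.9341 32.8335
2289.4 -81.1842 32.0852
2291.3 -131.2071 109.4807
2293.2 -73.5455 105.6969
2295.1 -55.8673 102.0784
2297.0 -45.0078 98.6172
2298.9 -37.2294 95.3056
2300.8 -31.2501 92.1365
2302.7 -26.4654 89.1031
2304.6 -22.5385 86.1989
2306.5 -19.2600 83.4178
2308.4 -16.4901 80.7539
2310.3 -14.1300 78.2018
2312.2 -12.1072 75.7562
2314.1 -10.3706 73.4122
2316.0 -29.2175 71.5396
2319.7 -26.2273 68.1123
2321.6 -24.9750 66.5052
2325.4 -22.8604 63.4876
2331.1 -20.4563 59.4086
2336.8 -18.7343 55.8033
2344.4 -17.1861 51.6277
2351.9 -16.2325 48.0627
2361.4 -15.5951 44.3134
2370.9 -15.3585 41.2038
2378.4 -15.3558 39.0921
2386.0 -15.4631 37.2585
2393.6 -15.6446 35.6602
2403.1 -15.9367 33.9397
2404.9 -29.6924 33.7831
2442.8 -27.5850 33.0375
2493.9 -25.4240 32.0633
2552.6 -23.6078 30.9889
2615.1 -22.2912 29.8945
2670.0 -21.7197 28.9727
2704.1 -21.8672 28.4186
2717.4 -22.1867 28.2068
2726.8 -22.6519 28.0567
2734.4 -23.4007 27.9374
2738.2 -24.1525 27.8780
2740.1 -24.8275 27.8483
2742.0 -26.2845 27.8187
2743.9 -26.4654 32.2631
2745.8 -24.7892 32.2320
2747.7 -24.0108 32.2010
2751.5 -23.0923 32.1390
2760.9 -21.8475 31.9848
2778.0 -20.5961 31.7099
2802.6 -19.4326 31.3185
2834.8 -18.3335 30.8169
2874.5 -17.2740 30.2124
2923.8 -16.2605 29.4874
2999.5 -15.0853 28.4191
3084.7 -14.2263 27.2723
3086.6 -14.3458 27.2476
3116.9 -14.2742 26.8569
3133.9 -14.5105 26.6409
3143.4 -15.0325 26.5220
3145.3 -15.3209 26.4984
3147.2 -16.0747 26.4747
3149.1 -15.6535 28.1924
3151.0 -15.1263 28.1671
3152.9 -14.8442 28.1418
3164.2 -14.0633 27.9911
3181.3 -13.4878 27.7677
3207.8 -12.9052 27.4264
3302.4 -11.6482 26.2657
3370.6 -11.2252 25.5143
3406.6 -11.2405 25.1311
3417.9 -11.4663 25.0120
3421.7 -11.7021 24.9725
3423.6 -11.9990 24.9528
3425.5 -12.2299 26.0194
3427.4 -11.7289 25.9996
3431.2 -11.3763 25.9600
3444.5 -10.8648 25.8223
3520.2 -9.6898 25.0569
3675.5 -8.3007 23.5940
3887.5 -7.0153 21.8032
4107.2 -6.0696 20.1648
4368.5 -5.2803 18.4513
4849.4 -4.3629 15.8278
5330.3 -3.9314 13.7475
5813.2 -3.7417 12.0613
6294.1 -3.7147 10.6849
6775.1 -3.7871 9.5389
7256.0 -3.9397 8.5757
7738.8 -4.1492 7.7552
8219.8 -4.4040 7.0550
8700.7 -4.7040 6.4498
9181.6 -5.0551 5.9206
9662.6 -5.4682 5.4558
10145.4 -5.9745 5.0443
10626.3 -6.6320 4.6811
11107.3 -7.5788 4.3579
11383.7 -8.4094 4.1879
11588.2 -9.3586 4.0688
11686.7 -10.0525 4.0134
11764.3 -10.8512 3.9705
11821.1 -11.7528 3.9396
11862.8 -12.8512 3.9172
11887.4 -13.9930 3.9041
11896.9 -14.7085 3.8990
11904.4 -15.5567 3.8950
11910.1 -16.5700 3.8920
11913.9 -17.7324 3.8899
11915.8 -18.7362 3.8889
11917.7 -20.8472 3.8879
11919.6 -21.1505 10.1998
11921.5 -18.8422 10.1970
11923.4 -17.7941 10.1941
11927.2 -16.5959 10.1884
11934.7 -15.3031 10.1771
11948.0 -14.0818 10.1572
11966.9 -13.0683 10.1290
11993.4 -12.1763 10.0897
12027.5 -11.4113 10.0396
12071.1 -10.7278 9.9760
12152.5 -9.8646 9.8590
12260.4 -9.1210 9.7072
12398.6 -8.4889 9.5183
12552.0 -8.0320 9.3168
12783.0 -7.5963 9.0298
13032.9 -7.3889 8.7340
13307.5 -7.4732 8.4255
13513.9 -7.9034 8.2043
13640.7 -8.6359 8.0726
13678.6 -9.1419 8.0339
13705.1 -9.7841 8.0069
13720.3 -10.5378 7.9916
13727.8 -11.3790 7.9839
13729.7 -11.7797 7.9820
13731.6 -12.4568 7.9801
13733.5 -15.6468 7.9782
13735.4 -12.5538 11.1598
13737.3 -11.8258 11.1571
13739.2 -11.4052 11.1545
13743.0 -10.8776 11.1493
13748.7 -10.3925 11.1414
13765.7 -9.6114 11.1178
13797.9 -8.8855 11.0736
13845.2 -8.3020 11.0090
13994.8 -7.4216 10.8086
14182.3 -7.0396 10.5655
14305.3 -7.3256 10.4104
14331.8 -7.6744 10.3775
14345.1 -8.1551 10.3611
14350.8 -8.8306 10.3541
14352.7 -10.2665 10.3517
14354.6 -8.8911 11.9728
14356.5 -8.5101 11.9704
14360.3 -8.1333 11.9655
14371.6 -7.6251 11.9508
14409.5 -6.9510 11.9023
14477.6 -6.4002 11.8166
14667.0 -5.5348 11.5836
14958.6 -4.7102 11.2380
15439.5 -3.7924 10.6960
15920.5 -3.1513 10.1927
16403.3 -2.6604 9.7238
16884.2 -2.2740 9.2893
17365.2 -1.9615 8.8843
17846.1 -1.7048 8.5063
18327.0 -1.4908 8.1522
18809.9 -1.3129 7.8194
19290.8 -1.1640 7.5085
19771.8 -1.0385 7.2164
20252.7 -0.9325 6.9416
20735.5 -0.8426 6.6817
21216.5 -0.7670 6.4376
21697.4 -0.7032 6.2069
22178.3 -0.6496 5.9889
22659.3 -0.6047 5.7824
23142.1 -0.5673 5.5860
23623.1 -0.5366 5.4005
24104.0 -0.5109 5.2242
24584.9 -0.4911 5.0567
25067.8 -0.4755 4.8967
25548.7 -0.4638 4.7449
26029.6 -0.4554 4.6003
26510.6 -0.4500 4.4624
26991.5 -0.4472 4.3304
27474.4 -0.4427 4.2035
27955.3 -0.4444 4.0825
28436.2 -0.4482 3.9668
28917.2 -0.4504 3.8560
29400.0 -0.4573 3.7494
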