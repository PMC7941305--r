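# Theoretical anomalous dispersion corrections for Pt (Z=78)
# Cromer-Liberman calculation, tabulated via the gemmi library.
# energy_eV f_prime f_doubleprime
1000.0 -26.8953 19.6213
1136.3 -25.8889 17.4428
1251.8 -25.5168 15.8967
1253.7 -25.3572 15.8730
1321.9 -25.3256 15.0442
1333.2 -25.2150 14.9107
1335.1 -24.4887 14.8886
1337.0 -25.0673 14.8663
1395.7 -25.0745 14.2007
1480.9 -25.4100 13.3149
1643.8 -26.5833 11.8689
1780.1 -28.3222 10.8546
1836.9 -29.3837 10.4749
1886.1 -30.5735 10.1636
1927.8 -31.8907 9.9122
1961.9 -33.3186 9.7141
1992.2 -35.0460 9.5436
2016.8 -37.0145 9.4086
2037.6 -39.4020 9.2969
2047.1 -40.8511 9.2469
2054.7 -42.2558 9.2071
2062.2 -43.9562 9.1677
2067.9 -45.4889 9.1383
2073.6 -47.3136 9.1091
2079.3 -49.5159 9.0800
2085.0 -52.2514 9.0510
2088.7 -54.4684 9.0317
2092.5 -57.1063 9.0125
2096.3 -60.3012 8.9934
2100.1 -64.2593 8.9744
2102.0 -66.6204 8.9649
2103.9 -69.3110 8.9554
2105.8 -72.4118 8.9459
2107.7 -76.0343 8.9365
2109.6 -80.3403 8.9271
2111.5 -85.5755 8.9177
2113.4 -92.1407 8.9083
2115.2 -100.7551 8.8989
2117.1 -112.9189 8.8895
2119.0 -132.7200 8.8802
2120.9 -182.9037 8.8708
2122.8 -160.5772 133.1976
2124.7 -118.5180 127.7138
2126.6 -96.6249 122.5042
2128.5 -81.8457 117.5539
2130.4 -70.8466 112.8485
2132.3 -62.2347 108.3749
2134.2 -55.2843 104.1205
2136.1 -49.5646 100.0733
2138.0 -44.7964 96.2225
2139.9 -40.7876 92.5573
2141.8 -37.3995 89.0680
2143.6 -34.5288 85.7453
2145.5 -32.0961 82.5803
2147.4 -30.0390 79.5648
2149.3 -28.3081 76.6910
2151.2 -26.8632 73.9515
2155.0 -24.7073 68.8481
2158.8 -23.3751 64.2034
2162.6 -22.7362 59.9720
2166.4 -22.7086 56.1130
2170.2 -23.2513 52.5902
2172.1 -23.7344 50.9446
2175.8 -25.1439 47.8662
2179.6 -27.2120 45.0490
2183.4 -30.0934 42.4683
2185.3 -31.9241 41.2595
2187.2 -34.0888 40.1018
2189.1 -36.6744 38.9927
2191.0 -39.8116 37.9298
2192.9 -43.7091 36.9110
2194.8 -48.7273 35.9342
2196.7 -55.5691 34.9975
2198.6 -65.9162 34.0991
2200.5 -85.9806 33.2370
2202.3 -118.6301 114.7044
2204.2 -71.7592 110.4410
2206.1 -54.2175 106.3759
2208.0 -43.1964 102.4988
2209.9 -35.2496 98.8001
2211.8 -29.1335 95.2707
2213.7 -24.2467 91.9020
2215.6 -20.2487 88.6859
2217.5 -16.9254 85.6147
2219.4 -14.1327 82.6811
2221.3 -11.7678 79.8784
2223.2 -9.7550 77.2000
2225.1 -8.0346 74.6397
2227.0 -28.0947 72.4206
2228.9 -26.5126 70.5275
2232.6 -23.8793 66.9892
2236.4 -21.8112 63.7548
2240.2 -20.1817 60.7951
2244.0 -18.8979 58.0839
2249.7 -17.4720 54.4325
2253.5 -16.7805 52.2453
2259.2 -16.0375 49.2902
2268.6 -15.3645 45.1069
2280.0 -15.1505 41.0732
2291.3 -15.3059 37.8700
2304.6 -15.7291 34.9251
2308.4 -15.8768 34.2094
2310.3 -17.5996 33.8697
2312.2 -30.0733 33.8308
2340.6 -28.3743 33.2557
2370.9 -26.8826 32.6556
2404.9 -25.4985 31.9965
2442.8 -24.2424 31.2835
2499.6 -22.8366 30.2505
2552.6 -22.0293 29.3246
2594.3 -21.8980 28.6221
2609.4 -22.0750 28.3718
2622.7 -22.4641 28.1552
2634.1 -23.2467 27.9711
2637.8 -23.7674 27.9101
2641.6 -24.7166 27.8492
2643.5 -25.7098 27.8189
2645.4 -32.7378 32.4623
2647.3 -25.6072 32.4260
2649.2 -24.5402 32.3898
2653.0 -23.4312 32.3176
2658.7 -22.4838 32.2100
2666.2 -21.6641 32.0678
2677.6 -20.8064 31.8571
2715.5 -19.0228 31.1762
2774.2 -17.2892 30.1810
2781.7 -17.1870 30.0632
2783.6 -17.4421 30.0341
2787.4 -17.1142 29.9762
2829.1 -16.2657 29.3494
2923.8 -14.9133 27.9908
2974.9 -14.5489 27.2949
3007.1 -14.6694 26.8689
3016.5 -14.9238 26.7446
3022.2 -15.3271 26.6705
3024.1 -15.6316 26.6458
3026.0 -16.4917 26.6212
3027.9 -15.8906 28.3719
3029.8 -15.3810 28.3452
3033.6 -14.8999 28.2919
3043.0 -14.3051 28.1595
3063.9 -13.6096 27.8721
3094.2 -12.9657 27.4635
3173.7 -11.8816 26.4411
3251.3 -11.3942 25.5515
3283.5 -11.5052 25.1966
3291.1 -11.7555 25.1142
3294.9 -12.2329 25.0732
3296.8 -12.3506 26.1538
3298.7 -11.8958 26.1331
3302.4 -11.5485 26.0918
3319.5 -10.9333 25.9071
3406.6 -9.6369 24.9949
3613.0 -7.9104 23.0281
3887.5 -6.4600 20.7696
4368.5 -4.9670 17.5608
4849.4 -4.2219 15.0534
5330.3 -3.8699 13.0704
5813.2 -3.7547 11.4624
6294.1 -3.7629 10.1496
6775.1 -3.8811 9.0584
7256.0 -4.0678 8.1418
7738.8 -4.3079 7.3613
8219.8 -4.5950 6.6953
8700.7 -4.9327 6.1197
9181.6 -5.3324 5.6167
9662.6 -5.8080 5.1744
10145.4 -6.4256 4.7831
10626.3 -7.2815 4.4382
10895.2 -7.9663 4.2623
11107.3 -8.7291 4.1313
11260.7 -9.5402 4.0405
11376.2 -10.4866 3.9742
11465.2 -11.7434 3.9243
11510.6 -12.9692 3.8991
11527.6 -13.7382 3.8897
11540.9 -14.6508 3.8824
11550.4 -15.7217 3.8772
11556.0 -16.8314 3.8741
11559.8 -18.1973 3.8720
11561.7 -19.5421 3.8710
11563.6 -25.7773 3.8700
11565.5 -19.7482 10.1946
11567.4 -18.3006 10.1918
11569.3 -17.4656 10.1890
11573.1 -16.4199 10.1833
11578.8 -15.4609 10.1748
11588.2 -14.4712 10.1606
11607.2 -13.3077 10.1323
11635.6 -12.2830 10.0902
11673.4 -11.4208 10.0344
11724.6 -10.6450 9.9598
11866.6 -9.3871 9.7569
12071.1 -8.4315 9.4756
12296.4 -7.8547 9.1795
12552.0 -7.5407 8.8602
12820.9 -7.5428 8.5421
13032.9 -7.9057 8.3031
13156.0 -8.4959 8.1690
13228.0 -9.4003 8.0920
13246.9 -9.9425 8.0719
13260.2 -10.6655 8.0579
13267.7 -11.6093 8.0499
13269.6 -12.1063 8.0479
13271.5 -13.1269 8.0459
13273.4 -13.4451 11.2408
13275.3 -12.2114 11.2380
13277.2 -11.6680 11.2353
13282.9 -10.8423 11.2270
13296.1 -9.9860 11.2078
13315.1 -9.3691 11.1804
13345.4 -8.7994 11.1369
13388.9 -8.2981 11.0747
13513.9 -7.5306 10.8993
13688.1 -7.0971 10.6621
13816.8 -7.2556 10.4919
13847.1 -7.5075 10.4525
13866.1 -7.9014 10.4280
13875.5 -8.4727 10.4157
13877.4 -8.7617 10.4133
13879.3 -9.5038 10.4109
13881.2 -9.0881 12.0417
13883.1 -8.6169 12.0392
13888.8 -8.0705 12.0315
13905.8 -7.4679 12.0086
13939.9 -6.9548 11.9632
13994.8 -6.4830 11.8914
14182.3 -5.5787 11.6510
14477.6 -4.7146 11.2869
14958.6 -3.7744 10.7248
15439.5 -3.1207 10.2046
15920.5 -2.6234 9.7227
16403.3 -2.2303 9.2738
16884.2 -1.9150 8.8579
17365.2 -1.6552 8.4702
17846.1 -1.4424 8.1078
18327.0 -1.2656 7.7690
18809.9 -1.1172 7.4505
19290.8 -0.9933 7.1530
19771.8 -0.8891 6.8735
20252.7 -0.8016 6.6107
20735.5 -0.7278 6.3621
21216.5 -0.6662 6.1286
21697.4 -0.6148 5.9081
22178.3 -0.5722 5.6996
22659.3 -0.5371 5.5022
23142.1 -0.5076 5.3145
23623.1 -0.4848 5.1371
24104.0 -0.4670 4.9687
24584.9 -0.4535 4.8086
25067.8 -0.4437 4.6558
25548.7 -0.4372 4.5109
26029.6 -0.4336 4.3729
26510.6 -0.4326 4.2412
26991.5 -0.4313 4.1149
27474.4 -0.4341 3.9935
27955.3 -0.4366 3.8780
28436.2 -0.4435 3.7675
28917.2 -0.4518 3.6618
29400.0 -0.4613 3.5603
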