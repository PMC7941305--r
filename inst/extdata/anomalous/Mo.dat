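# Theoretical anomalous dispersion corrections for Mo (Z=42)
# Cromer-Liberman calculation, tabulated via the gemmi library.
# energy_eV f_prime f_doubleprime
1000.0 -6.5914 10.8115
1045.4 -6.4135 10.2069
1102.2 -6.2747 9.5255
1157.2 -6.1964 8.9346
1215.9 -6.1587 8.3664
1276.4 -6.1547 7.8389
1340.8 -6.1840 7.3351
1409.0 -6.2466 6.8562
1480.9 -6.3435 6.4031
1598.3 -6.5418 5.7588
1721.4 -6.8438 5.1837
1846.4 -7.2557 4.6877
1961.9 -7.7393 4.2935
2054.7 -8.2236 4.0136
2138.0 -8.7655 3.7860
2211.8 -9.3678 3.6010
2274.3 -10.0125 3.4554
2302.7 -10.3646 3.3923
2329.2 -10.7388 3.3350
2353.8 -11.1369 3.2832
2374.7 -11.5229 3.2403
2393.6 -11.9249 3.2021
2412.5 -12.3911 3.1646
2427.7 -12.8260 3.1351
2442.8 -13.3364 3.1060
2452.3 -13.7072 3.0881
2461.8 -14.1316 3.0703
2469.3 -14.5220 3.0562
2476.9 -14.9729 3.0422
2484.5 -15.5074 3.0282
2490.2 -15.9858 3.0179
2495.8 -16.5612 3.0076
2499.6 -17.0226 3.0007
2503.4 -17.5755 2.9939
2505.3 -17.8995 2.9905
2507.2 -18.2667 2.9871
2509.1 -18.6907 2.9837
2511.0 -19.1928 2.9803
2512.9 -19.8090 2.9770
2514.8 -20.6083 2.9736
2516.7 -21.7508 2.9702
2518.6 -23.7870 2.9669
2520.4 -28.8448 11.3207
2522.3 -23.1075 11.3044
2524.2 -21.4256 11.2881
2526.1 -20.4080 11.2719
2528.0 -19.6785 11.2557
2529.9 -19.1112 11.2396
2531.8 -18.6484 11.2235
2533.7 -18.2586 11.2075
2535.6 -17.9227 11.1915
2539.4 -17.3677 11.1597
2543.2 -16.9227 11.1282
2548.8 -16.3942 11.0812
2554.5 -15.9824 11.0347
2560.2 -15.6551 10.9887
2565.9 -15.3938 10.9431
2573.5 -15.1300 10.8830
2581.0 -14.9512 10.8237
2586.7 -14.8711 10.7797
2594.3 -14.8422 10.7217
2600.0 -14.8909 10.6787
2605.7 -15.0223 10.6362
2609.4 -15.1766 10.6080
2613.2 -15.4147 10.5800
2615.1 -15.5817 10.5661
2617.0 -15.7977 10.5522
2618.9 -16.0887 10.5384
2620.8 -16.5092 10.5246
2622.7 -17.2133 10.5108
2624.6 -19.1867 10.4971
2626.5 -17.8344 14.6141
2628.4 -16.6417 14.5945
2630.3 -15.9865 14.5749
2632.2 -15.5226 14.5554
2634.1 -15.1582 14.5360
2635.9 -14.8554 14.5167
2637.8 -14.5945 14.4974
2641.6 -14.1568 14.4590
2643.5 -13.9681 14.4400
2645.4 -13.8827 14.4219
2653.0 -13.2927 14.3527
2660.6 -12.8158 14.2841
2671.9 -12.2294 14.1825
2683.3 -11.7441 14.0822
2698.4 -11.2028 13.9507
2713.6 -10.7485 13.8217
2730.6 -10.3157 13.6793
2749.6 -9.9126 13.5245
2789.3 -9.3245 13.2212
2806.4 -9.1488 13.0948
2821.5 -9.0546 12.9838
2832.9 -9.0407 12.9014
2842.3 -9.0915 12.8332
2849.9 -9.2090 12.7791
2855.6 -9.3929 12.7387
2859.4 -9.6241 12.7118
2861.3 -9.8176 12.6984
2863.2 -10.1458 12.6850
2865.1 -11.1179 12.6717
2867.0 -10.3773 14.5520
2868.8 -9.8447 14.5369
2870.7 -9.5457 14.5219
2872.6 -9.3316 14.5069
2876.4 -9.0198 14.4770
2882.1 -8.6869 14.4324
2889.7 -8.3566 14.3737
2899.1 -8.0327 14.3011
2910.5 -7.7140 14.2153
2923.8 -7.3991 14.1171
2938.9 -7.0869 14.0072
2957.8 -6.7449 13.8732
3007.1 -5.9862 13.5412
3056.3 -5.3773 13.2134
3113.1 -4.7890 12.8503
3177.5 -4.2276 12.4572
3247.5 -3.7114 12.0502
3325.2 -3.2297 11.6233
3406.6 -2.7989 11.2004
3512.6 -2.3315 10.6848
3626.2 -1.9186 10.1718
3747.4 -1.5531 9.6651
3887.5 -1.2147 9.1249
4109.1 -0.8086 8.3608
4368.5 -0.4717 7.5844
4601.4 -0.2636 6.9775
4849.4 -0.1080 6.4094
5086.1 0.0016 5.9303
5330.3 0.0752 5.4893
5565.1 0.1164 5.1106
5813.2 0.1426 4.7523
6294.1 0.1470 4.1583
6775.1 0.1171 3.6712
7256.0 0.0674 3.2663
7738.8 0.0072 2.9247
8219.8 -0.0607 2.6358
8700.7 -0.1316 2.3884
9181.6 -0.2033 2.1741
9662.6 -0.2753 1.9875
10145.4 -0.3482 1.8239
10626.3 -0.4203 1.6806
11107.3 -0.4889 1.5537
11588.2 -0.5579 1.4406
12071.1 -0.6300 1.3392
12552.0 -0.6990 1.2485
13032.9 -0.7720 1.1668
13513.9 -0.8463 1.0930
13994.8 -0.9225 1.0261
14477.6 -1.0021 0.9651
14958.6 -1.0853 0.9097
15439.5 -1.1740 0.8591
15920.5 -1.2699 0.8126
16403.3 -1.3762 0.7697
16884.2 -1.4956 0.7303
17365.2 -1.6341 0.6940
17846.1 -1.8005 0.6603
18327.0 -2.0108 0.6291
18809.9 -2.2992 0.6000
19071.2 -2.5133 0.5850
19290.8 -2.7507 0.5729
19446.1 -2.9720 0.5646
19576.7 -3.2170 0.5577
19684.7 -3.4895 0.5522
19771.8 -3.7936 0.5477
19841.8 -4.1438 0.5442
19870.2 -4.3349 0.5428
19894.8 -4.5394 0.5415
19915.7 -4.7555 0.5405
19934.6 -5.0060 0.5396
19949.7 -5.2673 0.5388
19963.0 -5.5732 0.5382
19972.5 -5.8707 0.5377
19980.0 -6.1973 0.5373
19985.7 -6.5411 0.5371
19989.5 -6.8616 0.5369
19991.4 -7.0714 0.5368
19993.3 -7.3375 0.5367
19995.2 -7.7014 0.5366
19997.1 -8.2799 0.5365
19999.0 -9.8075 0.5364
20000.9 -8.8653 3.6950
20002.8 -7.9897 3.6944
20004.7 -7.5280 3.6937
20006.5 -7.2122 3.6931
20008.4 -6.9719 3.6924
20010.3 -6.7777 3.6917
20012.2 -6.6147 3.6911
20016.0 -6.3509 3.6898
20021.7 -6.0509 3.6878
20029.3 -5.7523 3.6852
20040.6 -5.4226 3.6813
20055.8 -5.1014 3.6761
20072.8 -4.8294 3.6702
20093.6 -4.5711 3.6631
20116.4 -4.3468 3.6553
20142.9 -4.1337 3.6464
20175.1 -3.9215 3.6355
20252.7 -3.5351 3.6096
20343.6 -3.2086 3.5797
20453.4 -2.9115 3.5443
20584.1 -2.6386 3.5030
20735.5 -2.3893 3.4564
20983.6 -2.0750 3.3827
20985.5 -2.1005 3.3822
21216.5 -1.8731 3.3234
21697.4 -1.5151 3.2059
22178.3 -1.2509 3.0946
22659.3 -1.0445 2.9890
23142.1 -0.8767 2.8883
23623.1 -0.7381 2.7929
24104.0 -0.6212 2.7023
24584.9 -0.5212 2.6159
25067.8 -0.4347 2.5333
25548.7 -0.3597 2.4549
26029.6 -0.2940 2.3800
26510.6 -0.2362 2.3084
26991.5 -0.1845 2.2397
27474.4 -0.1386 2.1735
27955.3 -0.0984 2.1104
28436.2 -0.0627 2.0501
28917.2 -0.0309 1.9924
29400.0 -0.0024 1.9369
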