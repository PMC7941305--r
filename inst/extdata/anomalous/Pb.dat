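# Theoretical anomalous dispersion corrections for Pb (Z=82)
# Cromer-Liberman calculation, tabulated via the gemmi library.
# energy_eV f_prime f_doubleprime
1000.0 -28.2817 24.6494
1092.8 -26.7320 22.7209
1208.3 -25.4912 20.6550
1335.1 -24.6604 18.7307
1480.9 -24.2271 16.8619
1653.2 -24.1451 15.0174
1742.2 -24.3081 14.1749
1855.8 -24.8624 13.1950
1961.9 -25.6453 12.3784
2085.0 -26.9908 11.5310
2187.2 -28.6796 10.8974
2266.7 -30.6859 10.4432
2298.9 -31.8291 10.2681
2325.4 -33.0232 10.1275
2348.1 -34.3275 10.0094
2369.0 -35.8778 9.9032
2386.0 -37.5403 9.8176
2401.2 -39.4848 9.7425
2414.4 -41.7490 9.6776
2425.8 -44.3446 9.6225
2435.2 -47.2262 9.5770
2442.8 -50.2506 9.5409
2448.5 -53.1379 9.5139
2454.2 -56.7978 9.4871
2458.0 -59.8426 9.4692
2461.8 -63.5690 9.4514
2463.6 -65.7692 9.4426
2465.5 -68.2567 9.4337
2467.4 -71.0978 9.4249
2469.3 -74.3835 9.4161
2471.2 -78.2428 9.4072
2473.1 -82.8675 9.3984
2475.0 -88.5608 9.3897
2476.9 -95.8440 9.3809
2478.8 -105.7318 9.3721
2480.7 -120.6557 9.3634
2482.6 -149.6750 9.3546
2484.5 -194.0687 126.7944
2486.4 -129.0318 122.2080
2488.3 -104.1737 117.8302
2490.2 -88.4277 113.6505
2492.0 -76.9836 109.6591
2493.9 -68.1005 105.8464
2495.8 -60.9375 102.2036
2497.7 -55.0186 98.7223
2499.6 -50.0457 95.3944
2501.5 -45.8185 92.2125
2503.4 -42.1949 89.1695
2505.3 -39.0705 86.2585
2507.2 -36.3656 83.4731
2509.1 -34.0182 80.8074
2511.0 -31.9790 78.2555
2512.9 -30.2079 75.8121
2516.7 -27.3448 71.2301
2518.6 -26.2029 69.0821
2522.3 -24.4016 65.0498
2528.0 -22.6966 59.6015
2531.8 -22.1054 56.3277
2535.6 -21.8853 53.3110
2541.3 -22.1764 49.2188
2545.1 -22.7591 46.7501
2548.8 -23.6517 44.4682
2552.6 -24.8715 42.3571
2556.4 -26.4567 40.4023
2560.2 -28.4746 38.5908
2562.1 -29.6785 37.7349
2565.9 -32.5792 36.1162
2567.8 -34.3376 35.3508
2569.7 -36.3610 34.6130
2571.6 -38.7161 33.9017
2573.5 -41.4998 33.2159
2575.4 -44.8595 32.5544
2577.3 -49.0346 31.9163
2579.1 -54.4500 31.3006
2581.0 -61.9951 30.7065
2582.9 -74.0276 30.1330
2584.8 -102.7377 29.5794
2586.7 -95.6071 106.3987
2588.6 -68.3440 102.8370
2590.5 -54.5387 99.4356
2592.4 -45.2677 96.1865
2594.3 -38.3553 93.0820
2596.2 -32.9304 90.1148
2598.1 -28.5271 87.2781
2600.0 -24.8759 84.5653
2601.9 -21.8032 81.9704
2603.8 -19.1897 79.4875
2605.7 -16.9486 77.1112
2607.5 -33.5563 75.0670
2609.4 -31.6372 73.2181
2613.2 -28.4338 69.7574
2617.0 -25.8971 66.5877
2620.8 -23.8709 63.6812
2624.6 -22.2436 61.0131
2628.4 -20.9331 58.5612
2632.2 -19.8771 56.3055
2637.8 -18.6682 53.2509
2643.5 -17.8047 50.5445
2651.1 -17.0438 47.3999
2658.7 -16.6004 44.7041
2666.2 -16.3769 42.3833
2673.8 -16.3059 40.3773
2683.3 -16.3633 38.2376
2692.8 -16.5145 36.4345
2702.2 -16.7342 34.9061
2711.7 -16.9895 33.6033
2713.6 -28.3108 33.4417
2759.0 -26.1700 32.5867
2810.1 -24.3480 31.6633
2867.0 -22.8415 30.6824
2923.8 -21.7875 29.7461
2993.8 -21.1996 28.6489
3020.3 -21.3441 28.2479
3039.3 -21.7756 27.9663
3052.5 -22.5418 27.7715
3060.1 -23.5909 27.6611
3062.0 -24.1000 27.6336
3063.9 -24.9193 27.6061
3065.8 -26.9989 27.5787
3067.7 -25.9261 32.3818
3069.6 -24.4722 32.3474
3071.4 -23.7093 32.3130
3075.2 -22.7730 32.2446
3082.8 -21.6787 32.1085
3101.7 -20.1729 31.7733
3130.1 -18.8305 31.2839
3168.0 -17.6064 30.6548
3217.2 -16.4382 29.8748
3219.1 -16.6226 29.8487
3310.0 -15.0962 28.6471
3406.6 -13.9881 27.4504
3486.1 -13.4832 26.5214
3533.4 -13.6599 25.9908
3544.8 -13.9955 25.8659
3550.5 -14.4659 25.8037
3552.4 -14.8525 25.7831
3554.3 -16.6427 27.5549
3556.2 -14.7717 27.5315
3561.9 -13.9392 27.4617
3577.0 -13.1678 27.2773
3603.5 -12.5003 26.9602
3698.2 -11.2517 25.8844
3791.0 -10.7557 24.9538
3836.4 -10.8489 24.5288
3845.9 -11.1372 24.4417
3849.7 -11.6224 24.4070
3851.6 -11.6774 25.4489
3855.3 -11.0754 25.4141
3861.0 -10.7611 25.3621
3887.5 -10.1304 25.1214
3955.7 -9.3006 24.5190
4067.4 -8.3700 23.5773
4368.5 -6.7312 21.3023
4849.4 -5.2206 18.3203
5315.2 -4.4566 16.0041
5317.1 -4.0166 15.9956
5319.0 -4.3505 15.9871
5330.3 -4.3739 15.9364
5813.2 -3.9561 13.9982
6294.1 -3.7512 12.4140
6775.1 -3.6989 11.0949
7256.0 -3.7377 9.9844
7738.8 -3.8491 9.0359
8219.8 -4.0110 8.2253
8700.7 -4.2173 7.5243
9181.6 -4.4585 6.9106
9662.6 -4.7410 6.3713
10145.4 -5.0699 5.8944
10626.3 -5.4550 5.4737
11107.3 -5.9160 5.0987
11588.2 -6.4969 4.7626
12071.1 -7.3063 4.4593
12552.0 -8.6497 4.1866
12801.9 -10.0500 4.0553
12885.2 -10.8994 4.0129
12945.8 -11.8977 3.9826
12985.6 -13.0385 3.9629
13000.7 -13.7473 3.9554
13012.1 -14.5273 3.9498
13019.7 -15.3037 3.9461
13025.4 -16.1956 3.9433
13029.1 -17.1478 3.9415
13031.0 -17.8838 3.9405
13032.9 -19.0763 3.9396
13034.8 -22.6288 3.9387
13036.7 -19.8757 10.1275
13038.6 -18.2807 10.1250
13040.5 -17.4094 10.1226
13042.4 -16.8064 10.1201
13048.1 -15.6553 10.1127
13055.7 -14.7381 10.1029
13067.0 -13.8602 10.0882
13080.3 -13.1666 10.0711
13118.1 -11.9490 10.0225
13178.7 -10.8532 9.9454
13262.0 -9.9435 9.8408
13371.9 -9.1641 9.7051
13513.9 -8.4996 9.5336
13676.7 -7.9649 9.3423
13994.8 -7.3648 8.9799
14477.6 -7.0706 8.4692
14752.2 -7.2383 8.1980
14958.6 -7.6733 8.0027
15085.4 -8.3241 7.8861
15157.4 -9.2622 7.8211
15176.3 -9.8354 7.8042
15189.6 -10.6441 7.7923
15195.3 -11.4253 7.7872
15197.2 -11.9326 7.7856
15199.1 -13.0253 7.7839
15200.9 -13.0361 10.9185
15202.8 -11.9377 10.9162
15204.7 -11.4261 10.9139
15210.4 -10.6345 10.9069
15223.7 -9.8060 10.8909
15242.6 -9.2083 10.8679
15314.6 -8.1924 10.7815
15439.5 -7.4397 10.6338
15632.7 -6.9674 10.4115
15784.1 -7.0834 10.2421
15820.1 -7.3128 10.2025
15842.8 -7.6704 10.1776
15854.2 -8.1485 10.1652
15858.0 -8.5695 10.1611
15859.9 -9.1266 10.1590
15861.8 -9.1071 11.7476
15863.7 -8.5524 11.7455
15865.6 -8.2905 11.7433
15875.0 -7.7133 11.7325
15892.1 -7.2752 11.7132
15920.5 -6.8846 11.6810
16089.0 -5.8738 11.4940
16403.3 -4.9295 11.1577
16884.2 -4.0148 10.6682
17365.2 -3.3833 10.2091
17846.1 -2.8988 9.7804
18327.0 -2.5135 9.3791
18809.9 -2.1983 9.0016
19290.8 -1.9383 8.6487
19771.8 -1.7198 8.3168
20252.7 -1.5361 8.0042
20735.5 -1.3799 7.7085
21216.5 -1.2470 7.4305
21697.4 -1.1333 7.1679
22178.3 -1.0358 6.9194
22659.3 -0.9522 6.6840
23142.1 -0.8802 6.4600
23623.1 -0.8188 6.2482
24104.0 -0.7663 6.0470
24584.9 -0.7215 5.8557
25067.8 -0.6833 5.6729
25548.7 -0.6513 5.4994
26029.6 -0.6243 5.3340
26510.6 -0.6022 5.1761
26991.5 -0.5834 5.0247
27474.4 -0.5686 4.8790
27955.3 -0.5574 4.7404
28436.2 -0.5492 4.6078
28917.2 -0.5435 4.4809
29400.0 -0.5402 4.3590
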