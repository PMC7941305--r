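# Theoretical anomalous dispersion corrections for Ni (Z=28)
# Cromer-Liberman calculation, tabulated via the gemmi library.
# energy_eV f_prime f_doubleprime
1000.0 -9.5939 13.3992
1001.9 -9.6797 13.3620
1003.8 -9.8223 13.3249
1005.7 -10.0884 13.2880
1007.6 -10.9001 13.2513
1009.5 -10.2853 15.0250
1011.4 -9.7194 14.9860
1013.3 -9.3919 14.9472
1015.1 -9.1492 14.9085
1017.0 -8.9506 14.8700
1020.8 -8.6271 14.7935
1026.5 -8.2407 14.6801
1034.1 -7.8214 14.5311
1041.7 -7.4646 14.3846
1051.1 -7.0743 14.2050
1056.8 -6.8618 14.0991
1075.7 -6.2599 13.7647
1102.2 -5.5325 13.3175
1132.5 -4.8456 12.8333
1164.7 -4.2367 12.3480
1195.0 -3.7497 11.9165
1229.1 -3.2802 11.4581
1280.2 -2.6747 10.8194
1312.4 -2.3549 10.4438
1348.4 -2.0566 10.0439
1386.3 -1.7849 9.6480
1445.0 -1.4157 9.0799
1480.9 -1.2288 8.7546
1583.2 -0.8294 7.9205
1702.5 -0.5117 7.0934
1827.4 -0.2948 6.3616
1961.9 -0.1482 5.6964
2071.7 -0.0705 5.2285
2187.2 -0.0242 4.7966
2310.3 -0.0006 4.3939
2442.8 0.0040 4.0154
2671.9 -0.0215 3.4690
2923.8 -0.0783 2.9894
3156.7 -0.1457 2.6291
3406.6 -0.2259 2.3113
3637.6 -0.2947 2.0659
3887.5 -0.3806 1.8427
4368.5 -0.5456 1.5059
4849.4 -0.7035 1.2544
5330.3 -0.8680 1.0622
5813.2 -1.0425 0.9112
6294.1 -1.2372 0.7911
6775.1 -1.4729 0.6937
7256.0 -1.7914 0.6135
7523.0 -2.0401 0.5749
7738.8 -2.3165 0.5464
7911.1 -2.6304 0.5251
8045.6 -2.9927 0.5093
8098.6 -3.1897 0.5033
8145.9 -3.4111 0.4981
8185.7 -3.6492 0.4937
8219.8 -3.9153 0.4900
8248.2 -4.2117 0.4870
8272.8 -4.5685 0.4843
8291.7 -4.9670 0.4823
8299.3 -5.1830 0.4815
8306.9 -5.4559 0.4807
8312.5 -5.7205 0.4801
8316.3 -5.9429 0.4798
8320.1 -6.2244 0.4794
8323.9 -6.6077 0.4790
8325.8 -6.8670 0.4788
8327.7 -7.2091 0.4786
8329.6 -7.7124 0.4784
8331.5 -8.6798 0.4782
8333.4 -9.6185 3.9215
8335.3 -8.0086 3.9194
8337.2 -7.3801 3.9173
8339.0 -6.9814 3.9152
8340.9 -6.6886 3.9131
8344.7 -6.2649 3.9089
8348.5 -5.9580 3.9047
8352.3 -5.7171 3.9005
8356.1 -5.5185 3.8964
8361.8 -5.2736 3.8902
8375.0 -4.8489 3.8760
8390.2 -4.5013 3.8600
8411.0 -4.1483 3.8386
8435.6 -3.8350 3.8140
8465.9 -3.5384 3.7847
8500.0 -3.2764 3.7532
8539.8 -3.0315 3.7182
8587.1 -2.7959 3.6790
8640.1 -2.5805 3.6380
8700.7 -2.3776 3.5948
8742.4 -2.2572 3.5672
8744.2 -2.2760 3.5661
8833.2 -2.0452 3.5156
8945.0 -1.8019 3.4504
9181.6 -1.4101 3.3098
9405.1 -1.1398 3.1848
9662.6 -0.8992 3.0494
10145.4 -0.5728 2.8179
10626.3 -0.3466 2.6126
11107.3 -0.1793 2.4283
11588.2 -0.0560 2.2625
12071.1 0.0383 2.1127
12552.0 0.1108 1.9778
13032.9 0.1671 1.8554
13513.9 0.2111 1.7441
13994.8 0.2455 1.6424
14477.6 0.2723 1.5490
14958.6 0.2930 1.4637
15439.5 0.3087 1.3852
15920.5 0.3206 1.3127
16403.3 0.3297 1.2455
16884.2 0.3382 1.1834
17365.2 0.3417 1.1255
17846.1 0.3434 1.0718
18327.0 0.3437 1.0218
18809.9 0.3428 0.9750
19290.8 0.3410 0.9315
19771.8 0.3383 0.8909
20252.7 0.3350 0.8528
20735.5 0.3311 0.8170
21216.5 0.3268 0.7835
21697.4 0.3225 0.7520
22178.3 0.3176 0.7223
22659.3 0.3125 0.6943
23142.1 0.3072 0.6678
23623.1 0.3018 0.6429
24104.0 0.2963 0.6193
24584.9 0.2908 0.5970
25067.8 0.2853 0.5758
25548.7 0.2797 0.5557
26029.6 0.2742 0.5367
26510.6 0.2687 0.5186
26991.5 0.2633 0.5013
27474.4 0.2578 0.4848
27955.3 0.2524 0.4691
28436.2 0.2471 0.4542
28917.2 0.2419 0.4400
29400.0 0.2367 0.4264
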