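# Theoretical anomalous dispersion corrections for Fe (Z=26)
# Cromer-Liberman calculation, tabulated via the gemmi library.
# energy_eV f_prime f_doubleprime
1000.0 -3.8763 11.7209
1015.1 -3.6000 11.4838
1039.8 -3.2308 11.1131
1090.9 -2.5957 10.3992
1140.1 -2.1130 9.7759
1219.6 -1.4665 8.8793
1278.3 -1.1473 8.2862
1342.7 -0.8743 7.7036
1409.0 -0.6563 7.1675
1480.9 -0.4613 6.6464
1585.1 -0.2034 5.9888
1594.5 -0.1481 5.9341
1602.1 -0.0670 5.8908
1605.9 0.0076 5.8694
1609.7 0.1475 5.8480
1611.6 0.2795 5.8374
1613.5 0.5259 5.8268
1615.4 1.1575 5.8163
1617.3 6.5021 5.8057
1619.2 -2.7313 5.7952
1621.1 -1.3058 5.7848
1622.9 -0.9218 5.7743
1624.8 -0.7424 5.7639
1628.6 -0.5692 5.7432
1632.4 -0.4833 5.7226
1640.0 -0.3953 5.6817
1668.4 -0.2800 5.5322
1730.9 -0.1911 5.2240
1842.6 -0.1168 4.7350
1961.9 -0.0812 4.2865
2071.7 -0.0721 3.9286
2187.2 -0.0790 3.5994
2310.3 -0.0990 3.2929
2442.8 -0.1305 3.0052
2670.0 -0.1992 2.5940
2923.8 -0.2871 2.2282
3156.7 -0.3703 1.9557
3406.6 -0.4604 1.7159
3887.5 -0.6454 1.3646
4368.5 -0.8316 1.1130
4849.4 -1.0271 0.9262
5330.3 -1.2479 0.7835
5813.2 -1.5246 0.6716
6074.5 -1.7188 0.6209
6294.1 -1.9259 0.5826
6441.8 -2.1018 0.5589
6570.6 -2.2933 0.5394
6680.4 -2.5007 0.5236
6775.1 -2.7319 0.5105
6835.6 -2.9206 0.5024
6888.7 -3.1266 0.4954
6934.1 -3.3504 0.4896
6973.9 -3.6034 0.4846
7006.1 -3.8729 0.4806
7032.6 -4.1699 0.4773
7055.3 -4.5224 0.4746
7072.3 -4.9011 0.4725
7079.9 -5.1276 0.4716
7085.6 -5.3369 0.4709
7091.3 -5.5982 0.4702
7095.0 -5.8168 0.4698
7098.8 -6.0918 0.4693
7102.6 -6.4620 0.4689
7104.5 -6.7089 0.4686
7106.4 -7.0287 0.4684
7108.3 -7.4831 0.4682
7110.2 -8.2731 0.4680
7112.1 -11.6398 3.9517
7114.0 -8.1755 3.9495
7115.9 -7.4280 3.9473
7117.8 -6.9835 3.9452
7119.7 -6.6657 3.9430
7121.6 -6.4179 3.9409
7125.3 -6.0423 3.9366
7131.0 -5.6415 3.9302
7138.6 -5.2608 3.9217
7148.1 -4.9129 3.9111
7159.4 -4.5981 3.8985
7174.6 -4.2774 3.8818
7191.6 -3.9969 3.8633
7210.5 -3.7469 3.8429
7231.4 -3.5210 3.8208
7256.0 -3.2992 3.7950
7293.9 -3.0218 3.7562
7339.3 -2.7560 3.7108
7390.4 -2.5142 3.6614
7449.1 -2.2868 3.6065
7460.5 -2.2476 3.5962
7462.4 -2.2921 3.5945
7587.3 -1.9292 3.5042
7738.8 -1.6001 3.3990
7958.5 -1.2469 3.2539
8219.8 -0.9391 3.0922
8447.0 -0.7337 2.9605
8700.7 -0.5507 2.8222
9181.6 -0.2956 2.5831
9662.6 -0.1202 2.3734
10145.4 0.0078 2.1877
10626.3 0.1015 2.0237
11107.3 0.1713 1.8775
11588.2 0.2237 1.7466
12071.1 0.2632 1.6285
12552.0 0.2925 1.5223
13032.9 0.3143 1.4262
13513.9 0.3304 1.3388
13994.8 0.3417 1.2592
14477.6 0.3524 1.1858
14958.6 0.3564 1.1185
15439.5 0.3581 1.0569
15920.5 0.3586 1.0001
16403.3 0.3568 0.9476
16884.2 0.3539 0.8993
17365.2 0.3501 0.8545
17846.1 0.3456 0.8130
18327.0 0.3405 0.7744
18809.9 0.3350 0.7384
19290.8 0.3291 0.7049
19771.8 0.3231 0.6736
20252.7 0.3168 0.6443
20735.5 0.3105 0.6168
21216.5 0.3040 0.5911
21697.4 0.2976 0.5669
22178.3 0.2912 0.5441
22659.3 0.2848 0.5227
23142.1 0.2784 0.5025
23623.1 0.2721 0.4834
24104.0 0.2659 0.4654
24584.9 0.2598 0.4483
25067.8 0.2538 0.4321
25548.7 0.2478 0.4168
26029.6 0.2420 0.4023
26510.6 0.2364 0.3885
26991.5 0.2308 0.3754
27474.4 0.2253 0.3628
27955.3 0.2200 0.3509
28436.2 0.2147 0.3396
28917.2 0.2096 0.3288
29400.0 0.2046 0.3184
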