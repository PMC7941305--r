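# Theoretical anomalous dispersion corrections for Ca (Z=20)
# Cromer-Liberman calculation, tabulated via the gemmi library.
# energy_eV f_prime f_doubleprime
1000.0 -0.3238 4.4407
1100.4 -0.2784 3.8296
1214.0 -0.2810 3.2822
1338.9 -0.3195 2.8085
1480.9 -0.3769 2.3858
1587.0 -0.4369 2.1304
1700.6 -0.5045 1.9009
1961.9 -0.6616 1.4973
2187.2 -0.8019 1.2461
2442.8 -0.9642 1.0322
2923.8 -1.3068 0.7572
3192.6 -1.5517 0.6488
3406.6 -1.8085 0.5785
3573.2 -2.0823 0.5316
3705.8 -2.3909 0.4982
3808.0 -2.7407 0.4747
3851.6 -2.9458 0.4651
3887.5 -3.1593 0.4575
3929.2 -3.4890 0.4489
3963.3 -3.8807 0.4420
3978.4 -4.1212 0.4390
3989.8 -4.3483 0.4368
3999.2 -4.5852 0.4349
4008.7 -4.8917 0.4331
4016.3 -5.2219 0.4316
4022.0 -5.5590 0.4305
4025.7 -5.8598 0.4298
4029.5 -6.2739 0.4291
4031.4 -6.5577 0.4287
4033.3 -6.9380 0.4284
4035.2 -7.5150 0.4280
4037.1 -8.7412 0.4277
4039.0 -8.8542 4.0553
4040.9 -7.5421 4.0517
4042.8 -6.9394 4.0482
4044.7 -6.5428 4.0447
4046.6 -6.2463 4.0411
4048.5 -6.0091 4.0376
4052.3 -5.6414 4.0306
4056.0 -5.3602 4.0236
4059.8 -5.1320 4.0166
4069.3 -4.6983 3.9993
4080.7 -4.3227 3.9787
4095.8 -3.9512 3.9516
4114.7 -3.6020 3.9183
4139.4 -3.2565 3.8758
4165.9 -2.9664 3.8311
4198.1 -2.6851 3.7782
4235.9 -2.4185 3.7180
4237.8 -2.4405 3.7152
4298.4 -2.1077 3.6339
4368.5 -1.8091 3.5433
4463.1 -1.4959 3.4261
4574.9 -1.2110 3.2952
4703.6 -0.9561 3.1534
4849.4 -0.7306 3.0038
5070.9 -0.4728 2.7961
5330.3 -0.2545 2.5791
5813.2 0.0072 2.2368
6294.1 0.1619 1.9593
6775.1 0.2572 1.7301
7256.0 0.3156 1.5387
7738.8 0.3509 1.3764
8219.8 0.3713 1.2386
8700.7 0.3806 1.1203
9181.6 0.3840 1.0174
9662.6 0.3821 0.9277
10145.4 0.3765 0.8491
10626.3 0.3686 0.7802
11107.3 0.3592 0.7194
11588.2 0.3491 0.6653
12071.1 0.3383 0.6169
12552.0 0.3274 0.5737
13032.9 0.3165 0.5349
13513.9 0.3057 0.4998
13994.8 0.2950 0.4680
14477.6 0.2846 0.4390
14958.6 0.2745 0.4126
15439.5 0.2648 0.3886
15920.5 0.2554 0.3665
16403.3 0.2463 0.3462
16884.2 0.2375 0.3275
17365.2 0.2291 0.3103
17846.1 0.2221 0.2943
18327.0 0.2143 0.2795
18809.9 0.2067 0.2657
19290.8 0.1995 0.2529
19771.8 0.1925 0.2411
20252.7 0.1859 0.2300
20735.5 0.1795 0.2196
21216.5 0.1734 0.2099
21697.4 0.1675 0.2009
22178.3 0.1619 0.1924
22659.3 0.1565 0.1844
23142.1 0.1513 0.1769
23623.1 0.1463 0.1698
24104.0 0.1416 0.1632
24584.9 0.1370 0.1569
25067.8 0.1325 0.1509
25548.7 0.1283 0.1453
26029.6 0.1242 0.1400
26510.6 0.1202 0.1350
26991.5 0.1165 0.1302
27474.4 0.1128 0.1256
27955.3 0.1093 0.1212
28436.2 0.1059 0.1170
28917.2 0.1026 0.1131
29400.0 0.0995 0.1093
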