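# Theoretical anomalous dispersion corrections for Mn (Z=25)
# Cromer-Liberman calculation, tabulated via the gemmi library.
# energy_eV f_prime f_doubleprime
1000.0 -2.5933 10.2327
1036.0 -2.2064 9.7403
1102.2 -1.5955 8.9198
1143.9 -1.3299 8.4496
1187.5 -1.1014 7.9979
1255.6 -0.8218 7.3625
1327.6 -0.5950 6.7720
1401.4 -0.4331 6.2374
1480.9 -0.3093 5.7314
1587.0 -0.2028 5.1493
1702.5 -0.1381 4.6130
1827.4 -0.1086 4.1238
1961.9 -0.1077 3.6812
2071.7 -0.1225 3.3714
2187.2 -0.1484 3.0867
2442.8 -0.2278 2.5735
2671.9 -0.3106 2.2161
2923.8 -0.4109 1.9039
3158.5 -0.5004 1.6680
3406.6 -0.6013 1.4634
3887.5 -0.7996 1.1627
4368.5 -1.0068 0.9476
4849.4 -1.2402 0.7881
5330.3 -1.5341 0.6663
5593.5 -1.7469 0.6114
5813.2 -1.9782 0.5708
5968.4 -2.1926 0.5445
6099.1 -2.4292 0.5237
6207.0 -2.6916 0.5075
6294.1 -2.9823 0.4949
6369.9 -3.3455 0.4844
6400.1 -3.5432 0.4803
6426.7 -3.7581 0.4767
6449.4 -3.9903 0.4737
6468.3 -4.2372 0.4712
6485.4 -4.5274 0.4690
6498.6 -4.8291 0.4673
6510.0 -5.1836 0.4658
6517.5 -5.5107 0.4648
6523.2 -5.8454 0.4641
6527.0 -6.1454 0.4636
6528.9 -6.3339 0.4634
6530.8 -6.5620 0.4631
6532.7 -6.8509 0.4629
6534.6 -7.2444 0.4626
6536.5 -7.8633 0.4624
6538.4 -9.4009 0.4622
6540.3 -8.6387 3.9618
6542.2 -7.6137 3.9595
6544.0 -7.0864 3.9572
6545.9 -6.7283 3.9549
6547.8 -6.4564 3.9526
6549.7 -6.2371 3.9503
6551.6 -6.0531 3.9480
6555.4 -5.7554 3.9435
6561.1 -5.4166 3.9367
6568.7 -5.0790 3.9276
6580.0 -4.7052 3.9141
6593.3 -4.3802 3.8985
6610.3 -4.0609 3.8786
6629.3 -3.7837 3.8568
6650.1 -3.5377 3.8331
6676.6 -3.2829 3.8034
6705.0 -3.0585 3.7721
6775.1 -2.6358 3.6974
6860.3 -2.2662 3.6109
6862.2 -2.3066 3.6092
6989.0 -1.9096 3.5082
7112.1 -1.6205 3.4141
7256.0 -1.3552 3.3086
7477.5 -1.0431 3.1553
7738.8 -0.7695 2.9874
8219.8 -0.4215 2.7105
8700.7 -0.1911 2.4691
9181.6 -0.0327 2.2578
9662.6 0.0800 2.0725
10145.4 0.1620 1.9085
10626.3 0.2216 1.7639
11107.3 0.2654 1.6350
11588.2 0.2973 1.5198
12071.1 0.3209 1.4159
12552.0 0.3374 1.3226
13032.9 0.3483 1.2381
13513.9 0.3587 1.1608
13994.8 0.3620 1.0904
14477.6 0.3636 1.0260
14958.6 0.3623 0.9673
15439.5 0.3596 0.9135
15920.5 0.3557 0.8640
16403.3 0.3509 0.8182
16884.2 0.3454 0.7761
17365.2 0.3395 0.7372
17846.1 0.3331 0.7010
18327.0 0.3265 0.6675
18809.9 0.3197 0.6361
19290.8 0.3128 0.6070
19771.8 0.3058 0.5799
20252.7 0.2989 0.5544
20735.5 0.2919 0.5305
21216.5 0.2850 0.5082
21697.4 0.2782 0.4873
22178.3 0.2714 0.4675
22659.3 0.2648 0.4490
23142.1 0.2583 0.4314
23623.1 0.2519 0.4149
24104.0 0.2456 0.3993
24584.9 0.2395 0.3846
25067.8 0.2335 0.3706
25548.7 0.2276 0.3573
26029.6 0.2219 0.3448
26510.6 0.2163 0.3329
26991.5 0.2109 0.3215
27474.4 0.2055 0.3107
27955.3 0.2003 0.3004
28436.2 0.1981 0.2906
28917.2 0.1931 0.2812
29400.0 0.1881 0.2721
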