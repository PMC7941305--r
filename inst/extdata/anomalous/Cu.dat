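# Theoretical anomalous dispersion corrections for Cu (Z=29)
# Cromer-Liberman calculation, tabulated via the gemmi library.
# energy_eV f_prime f_doubleprime
1000.0 -11.8839 15.9374
1005.7 -11.4181 15.7257
1011.4 -11.0012 15.5197
1017.0 -10.6267 15.3191
1024.6 -10.1855 15.0597
1026.5 -10.6708 15.0071
1036.0 -10.2018 14.7630
1045.4 -9.8037 14.5263
1047.3 -10.0395 14.4814
1056.8 -9.7161 14.2867
1064.4 -9.5062 14.1337
1072.0 -9.3479 13.9832
1079.5 -9.2617 13.8350
1085.2 -9.2778 13.7254
1089.0 -9.3670 13.6531
1090.9 -9.4605 13.6171
1092.8 -9.6246 13.5813
1094.7 -9.9826 13.5456
1096.6 -10.4738 15.0500
1098.5 -9.6306 15.0242
1100.4 -9.2904 14.9984
1102.2 -9.0575 14.9728
1106.0 -8.7165 14.9216
1109.8 -8.4526 14.8706
1119.3 -7.9352 14.7439
1132.5 -7.3624 14.5681
1149.6 -6.7467 14.3437
1151.5 -6.4930 14.3129
1153.4 -6.4307 14.2803
1166.6 -6.0234 14.0550
1179.9 -5.6580 13.8352
1212.1 -4.8990 13.3232
1236.7 -4.4112 12.9514
1265.1 -3.9234 12.5420
1293.5 -3.5000 12.1524
1325.7 -3.0831 11.7331
1391.9 -2.3641 10.9372
1429.8 -2.0315 10.5180
1480.9 -1.6677 9.9869
1524.5 -1.4079 9.5666
1573.7 -1.1581 9.1236
1687.3 -0.7258 8.2152
1819.9 -0.3905 7.3209
1961.9 -0.1638 6.5190
2071.7 -0.0513 5.9877
2187.2 0.0259 5.4973
2310.3 0.0771 5.0387
2442.8 0.1011 4.6073
2671.9 0.0977 3.9839
2923.8 0.0548 3.4362
3156.7 -0.0053 3.0238
3406.6 -0.0813 2.6596
3635.7 -0.1558 2.3818
3887.5 -0.2311 2.1240
4368.5 -0.3933 1.7366
4849.4 -0.5480 1.4480
5330.3 -0.7039 1.2265
5813.2 -0.8619 1.0524
6294.1 -1.0275 0.9141
6775.1 -1.2109 0.8018
7256.0 -1.4284 0.7092
7738.8 -1.7129 0.6318
8000.1 -1.9184 0.5952
8219.8 -2.1422 0.5668
8373.1 -2.3446 0.5482
8501.9 -2.5629 0.5333
8609.8 -2.8019 0.5213
8700.7 -3.0710 0.5115
8749.9 -3.2596 0.5063
8793.5 -3.4666 0.5017
8829.5 -3.6812 0.4980
8861.6 -3.9255 0.4948
8888.2 -4.1868 0.4921
8910.9 -4.4841 0.4898
8927.9 -4.7846 0.4881
8943.1 -5.1553 0.4866
8950.6 -5.4067 0.4858
8958.2 -5.7387 0.4850
8963.9 -6.0818 0.4845
8967.7 -6.3937 0.4841
8969.6 -6.5924 0.4839
8971.5 -6.8367 0.4837
8973.4 -7.1537 0.4835
8975.3 -7.6054 0.4833
8977.1 -8.3975 0.4832
8979.0 -11.1707 3.9026
8980.9 -8.2448 3.9010
8982.8 -7.5252 3.8994
8984.7 -7.0942 3.8977
8986.6 -6.7852 3.8961
8988.5 -6.5439 3.8944
8992.3 -6.1778 3.8912
8996.1 -5.9027 3.8879
8999.9 -5.6821 3.8846
9007.4 -5.3393 3.8781
9018.8 -4.9647 3.8684
9032.1 -4.6422 3.8572
9049.1 -4.3275 3.8428
9068.0 -4.0555 3.8270
9090.8 -3.7953 3.8081
9117.3 -3.5501 3.7864
9147.6 -3.3206 3.7620
9181.6 -3.1064 3.7348
9272.5 -2.6733 3.6646
9386.1 -2.2905 3.5807
9420.2 -2.1968 3.5564
9422.1 -2.2354 3.5552
9533.8 -1.9729 3.4902
9662.6 -1.7296 3.4174
9884.1 -1.4048 3.2973
10145.4 -1.1171 3.1637
10626.3 -0.7422 2.9380
11107.3 -0.4838 2.7355
11588.2 -0.2955 2.5531
12071.1 -0.1488 2.3860
12552.0 -0.0406 2.2352
13032.9 0.0436 2.0983
13513.9 0.1098 1.9736
13994.8 0.1621 1.8597
14477.6 0.2037 1.7550
14958.6 0.2367 1.6593
15439.5 0.2627 1.5711
15920.5 0.2833 1.4898
16403.3 0.2993 1.4142
16884.2 0.3116 1.3445
17365.2 0.3209 1.2798
17846.1 0.3278 1.2196
17955.9 0.3298 1.2065
17957.8 0.2810 1.2063
17959.7 0.3309 1.2060
17961.6 0.3313 1.2058
18327.0 0.3347 1.1633
18809.9 0.3374 1.1105
19290.8 0.3385 1.0614
19771.8 0.3385 1.0154
20252.7 0.3375 0.9724
20735.5 0.3357 0.9319
21216.5 0.3331 0.8940
21697.4 0.3301 0.8583
22178.3 0.3265 0.8247
22659.3 0.3226 0.7930
23142.1 0.3183 0.7630
23623.1 0.3140 0.7348
24104.0 0.3092 0.7080
24584.9 0.3044 0.6827
25067.8 0.2994 0.6586
25548.7 0.2943 0.6359
26029.6 0.2892 0.6142
26510.6 0.2840 0.5937
26991.5 0.2788 0.5741
27474.4 0.2736 0.5553
27955.3 0.2684 0.5375
28436.2 0.2633 0.5205
28917.2 0.2581 0.5043
29400.0 0.2530 0.4888
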