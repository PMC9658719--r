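# kind: molar_absorption
wavelength_nm,value
       440,93420.9672
       441,92645.6939
       442,91876.8544
       443,91114.3953
       444,90358.2636
       445,89608.4068
       446,88864.7728
       447,88127.3101
       448,87395.9673
       449,86670.6938
       450,85951.4391
       451,85238.1532
       452,84530.7867
       453,83829.2905
       454,83133.6157
       455,82443.7142
       456,81759.5379
       457,81081.0394
       458,80408.1716
       459,79740.8877
       460,79079.1414
       461,78422.8868
       462,77772.0782
       463,77126.6705
       464,76486.6188
       465,75851.8788
       466,75222.4062
       467,74598.1575
       468,73979.0893
       469,73365.1586
       470,72756.3229
       471,72152.5398
       472,71553.7677
       473,70959.9652
       474,70371.0913
       475,69787.1058
       476,69207.9691
       477,68633.6426
       478,68064.0893
       479,67499.2737
       480,66939.1636
       481,66383.7309
       482,65832.9543
       483,65286.8221
       484,64745.3373
       485,64208.5248
       486,63676.4418
       487,63149.1928
       488, 62626.951
       489,62109.9882
       490,61598.7166
       491,61093.7468
       492,60595.9648
       493, 60106.638
       494,59627.5531
       495,59161.1982
       496,58710.9971
       497,58281.6079
       498,57879.2971
       499,57512.4025
       500,57191.8947
       501,56932.0493
       502,56751.2334
       503,56672.8094
       504,56726.1487
       505,56947.7381
       506,57382.3515
       507,  58084.24
       508,59118.2819
       509,60561.0108
       510,62501.4249
       511, 65041.461
       512,68296.0051
       513,72392.3002
       514,77468.6148
       515,83672.0391
       516,91155.3052
       517,100072.555
       518,110574.032
       519,122799.743
       520,136872.188
       521,152888.377
       522,170911.401
       523,190961.931
       524, 213010.09
       525,236968.198
       526,262684.909
       527,289941.285
       528,318449.282
       529,347853.077
       530,377733.513
       531, 407615.82
       532,436980.581
       533,465277.697
       534,491942.942
       535,516416.484
       536,538162.615
       537,556689.778
       538,571569.969
       539, 582456.53
       540,589099.452
       541,591357.398
       542,589205.836
       543,582740.883
       544,572178.687
       545, 557850.41
       546,540193.107
       547,519736.961
       548,497089.524
       549,472917.641
       550,447927.837
       551,422845.876
       552,398396.173
       553,375281.612
       554,354164.261
       555,335647.311
       556, 320258.54
       557,308435.486
       558,300512.536
       559,296710.128
       560,297126.322
       561,301731.037
       562,310363.342
       563,322732.198
       564,338421.062
       565,356896.709
       566,377522.484
       567,399576.026
       568,422271.224
       569,  444783.9
       570,466280.364
       571,485947.723
       572,503024.554
       573,516830.391
       574,526792.433
       575,532467.912
       576,533560.795
       577,529931.779
       578,521600.941
       579,508742.909
       580,491674.868
       581,470838.214
       582,446775.068
       583,420101.145
       584,391476.698
       585,361577.257
       586,331065.835
       587,300568.037
       588,270651.228
       589,241808.539
       590,214448.114
       591,188887.611
       592,165353.629
       593,143985.472
       594,124842.429
       595,107913.683
       596, 93129.875
       597,80375.4554
       598,69500.9848
       599,60334.7514
       600,52693.1924
       601, 46389.797
       602,41242.3188
       603,37078.2682
       604,33738.7685
       605,31080.9371
       606,28979.0125
       607,27324.4656
       608,26025.3432
       609,25005.0696
       610,24200.9126
       611,23562.2797
       612,23048.9793
       613,22629.5444
       614,22279.6845
       615,21980.9049
       616,21719.3116
       617,21484.6029
       618,21269.2381
       619,21067.7665
       620,20876.2961
       621,20692.0812
       622,20513.2069
       623, 20338.353
       624,20166.6186
       625,19997.3949
       626,19830.2743
       627,19664.9853
       628,19501.3481
       629,19339.2433
       630,19178.5911
       631,19019.3378
       632,18861.4455
       633, 18704.887
       634,18549.6418
       635, 18395.693
       636,18243.0264
       637,18091.6295
       638,17941.4905
       639,17792.5983
       640,17644.9421
       641,17498.5116
       642,17353.2964
       643,17209.2864
       644,17066.4715
       645,16924.8419
       646,16784.3876
       647,16645.0988
       648, 16506.966
       649,16369.9795
       650,16234.1299
       651,16099.4076
       652,15965.8033
       653,15833.3078
       654,15701.9118
       655,15571.6062
       656, 15442.382
       657,15314.2302
       658,15187.1419
       659,15061.1082
       660,14936.1205
       661,  14812.17
       662,14689.2482
       663,14567.3464
       664,14446.4562
       665,14326.5693
       666,14207.6773
       667, 14089.772
       668,13972.8451
       669,13856.8885
       670,13741.8943
       671,13627.8543
       672,13514.7607
       673,13402.6057
       674,13291.3814
       675,13181.0801
       676,13071.6942
       677, 12963.216
       678,12855.6381
       679,12748.9529
       680,12643.1531
       681,12538.2312
       682,12434.1801
       683,12330.9925
       684,12228.6612
       685,12127.1791
       686,12026.5392
       687,11926.7345
       688, 11827.758
       689,11729.6029
       690,11632.2623
       691,11535.7296
       692, 11439.998
       693,11345.0608
       694,11250.9114
       695,11157.5434
       696,11064.9502
       697,10973.1254
       698,10882.0627
       699,10791.7556
       700, 10702.198
       701,10613.3836
       702,10525.3062
       703,10437.9598
       704,10351.3382
       705,10265.4355
       706,10180.2456
       707,10095.7628
       708, 10011.981
       709,9928.89449
       710, 9846.4975
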