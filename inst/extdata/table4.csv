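process,n_target,mean_3y,sd_3y,mean_5y,sd_5y
PROCESS_2015,1000,636,15,861,8.0
PROCESS_2015,1500,939,17,1281,8.9
PROCESS_2015,2000,1227,20,1694,9.7
PROCESS_2015,2500,1491,18,2094,12
PROCESS_2015,3000,1693,21,2448,14
PROCESS_2015,3500,NA,NA,NA,NA
PROCESS_2015,4000,NA,NA,NA,NA
RANDOM,1000,515,15,791,13
RANDOM,1500,774,22,1185,17
RANDOM,2000,1034,27,1580,22
RANDOM,2500,1293,30,1976,25
RANDOM,3000,1551,31,2370,28
RANDOM,3500,1811,36,2764,30
RANDOM,4000,2056,38,3138,39
STAGE2_ONLY,1000,673,14,881,5.9
STAGE2_ONLY,1500,985,17,1308,7.2
STAGE2_ONLY,2000,1283,21,1726,8.7
STAGE2_ONLY,2500,1553,21,2217,10
STAGE2_ONLY,3000,1791,23,2512,15
STAGE2_ONLY,3500,1983,28,2873,21
STAGE2_ONLY,4000,2115,32,3178,37
STAGE3_ONLY,1000,596,12,842,8.4
STAGE3_ONLY,1500,886,17,1256,11
STAGE3_ONLY,2000,1171,19,1668,11
STAGE3_ONLY,2500,1442,20,2072,13
STAGE3_ONLY,3000,1692,23,2466,15
STAGE3_ONLY,3500,1910,26,2841,19
STAGE3_ONLY,4000,2091,32,3615,34
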