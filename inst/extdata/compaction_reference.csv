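protein,metric,phase,field,mean,sd
trp_cage,ccs,solution,NA,381,7
trp_cage,ccs,vacuum,0.0,361,4
trp_cage,ccs,rehydration,0.0,386,12
trp_cage,ccs,vacuum,0.2,357,5
trp_cage,ccs,rehydration,0.2,383,12
trp_cage,ccs,vacuum,0.4,357,8
trp_cage,ccs,rehydration,0.4,383,8
ctf,ccs,solution,NA,819,9
ctf,ccs,vacuum,0.0,781,4
ctf,ccs,rehydration,0.0,857,28
ctf,ccs,vacuum,0.2,791,12
ctf,ccs,rehydration,0.2,860,37
ctf,ccs,vacuum,0.4,794,10
ctf,ccs,rehydration,0.4,874,25
ubiquitin,ccs,solution,NA,889,12
ubiquitin,ccs,vacuum,0.0,851,14
ubiquitin,ccs,rehydration,0.0,929,23
ubiquitin,ccs,vacuum,0.2,852,9
ubiquitin,ccs,rehydration,0.2,922,21
ubiquitin,ccs,vacuum,0.4,841,7
ubiquitin,ccs,rehydration,0.4,911,18
lysozyme,ccs,solution,NA,1249,11
lysozyme,ccs,vacuum,0.0,1186,10
lysozyme,ccs,rehydration,0.0,1278,21
lysozyme,ccs,vacuum,0.2,1182,12
lysozyme,ccs,rehydration,0.2,1284,18
lysozyme,ccs,vacuum,0.4,1179,12
lysozyme,ccs,rehydration,0.4,1273,20
trp_cage,sasa,solution,NA,1937,63
trp_cage,sasa,vacuum,0.0,1294,113
trp_cage,sasa,rehydration,0.0,1959,81
trp_cage,sasa,vacuum,0.2,1079,244
trp_cage,sasa,rehydration,0.2,1946,82
trp_cage,sasa,vacuum,0.4,1241,113
trp_cage,sasa,rehydration,0.4,1952,69
ctf,sasa,solution,NA,4520,110
ctf,sasa,vacuum,0.0,3781,179
ctf,sasa,rehydration,0.0,4813,226
ctf,sasa,vacuum,0.2,3975,282
ctf,sasa,rehydration,0.2,4863,248
ctf,sasa,vacuum,0.4,3805,160
ctf,sasa,rehydration,0.4,4921,227
ubiquitin,sasa,solution,NA,4765,109
ubiquitin,sasa,vacuum,0.0,3791,25
ubiquitin,sasa,rehydration,0.0,5087,165
ubiquitin,sasa,vacuum,0.2,4083,143
ubiquitin,sasa,rehydration,0.2,5093,177
ubiquitin,sasa,vacuum,0.4,3827,177
ubiquitin,sasa,rehydration,0.4,4969,162
lysozyme,sasa,solution,NA,7052,127
lysozyme,sasa,vacuum,0.0,6035,131
lysozyme,sasa,rehydration,0.0,7335,181
lysozyme,sasa,vacuum,0.2,6013,273
lysozyme,sasa,rehydration,0.2,7367,159
lysozyme,sasa,vacuum,0.4,5954,253
lysozyme,sasa,rehydration,0.4,7347,216
trp_cage,volume,solution,NA,4743,100
trp_cage,volume,vacuum,0.0,3171,269
trp_cage,volume,rehydration,0.0,4750,111
trp_cage,volume,vacuum,0.2,2624,516
trp_cage,volume,rehydration,0.2,4750,111
trp_cage,volume,vacuum,0.4,3070,234
trp_cage,volume,rehydration,0.4,4753,105
ctf,volume,solution,NA,13979,194
ctf,volume,vacuum,0.0,12133,702
ctf,volume,rehydration,0.0,14360,281
ctf,volume,vacuum,0.2,12666,856
ctf,volume,rehydration,0.2,14403,298
ctf,volume,vacuum,0.4,11884,544
ctf,volume,rehydration,0.4,14450,293
ubiquitin,volume,solution,NA,16417,217
ubiquitin,volume,vacuum,0.0,13068,141
ubiquitin,volume,rehydration,0.0,16812,231
ubiquitin,volume,vacuum,0.2,13967,516
ubiquitin,volume,rehydration,0.2,16773,261
ubiquitin,volume,vacuum,0.4,13334,578
ubiquitin,volume,rehydration,0.4,16597,288
lysozyme,volume,solution,NA,26066,298
lysozyme,volume,vacuum,0.0,23176,784
lysozyme,volume,rehydration,0.0,26270,357
lysozyme,volume,vacuum,0.2,23158,1017
lysozyme,volume,rehydration,0.2,26314,332
lysozyme,volume,vacuum,0.4,23221,937
lysozyme,volume,rehydration,0.4,26367,387
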