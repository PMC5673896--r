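mz,intensity,snr
258.5337271029,5.49535790644586,5.49535790644586
287.0408184054,79.6649981454722,79.6649981454722
291.1601756177,43.3008258625841,43.3008258625841
303.2653376471,148.960746410356,148.960746410356
317.2809286426,27.5470037841788,27.5470037841788
326.2700681148,130.473078199158,130.473078199158
340.6463531218,4.91631803801283,4.91631803801283
381.0310118927,170.933457284468,170.933457284468
411.1084451189,188.4228033594,188.4228033594
423.1297019801,33.5017602991282,33.5017602991282
433.3323190414,185.120349371188,185.120349371188
447.3480406194,48.9216220680048,48.9216220680048
465.1765976172,943.102002051235,943.102002051235
495.2024141949,69.4980916381078,69.4980916381078
501.3699009221,283.244486070196,283.244486070196
514.3287144881,4.16905614593998,4.16905614593998
521.2392176978,115.682784219033,115.682784219033
606.0794462020,28.8074344251975,28.8074344251975
620.0950763591,72.5983384117858,72.5983384117858
643.1666346899,99.6506226411532,99.6506226411532
646.1875260482,2.89646948920563,2.89646948920563
669.0063942192,84.5200987348272,84.5200987348272
713.2451226418,23.6213813026116,23.6213813026116
739.1058343788,170.609441455692,170.609441455692
779.3132177611,731.309131230459,731.309131230459
803.6042092165,19.9295515070304,19.9295515070304
821.3600093868,113.331971525888,113.331971525888
896.2467590903,21.0079270554975,21.0079270554975
909.3389179651,4.06408934341744,4.06408934341744
938.2937478058,70.7709648156123,70.7709648156123
952.3091660955,130.980142564001,130.980142564001
959.0549065453,42.6501584508478,42.6501584508478
962.0906972745,4.06156443059444,4.06156443059444
966.3247932250,39.3220796996031,39.3220796996031
980.3403655730,21.7381530876163,21.7381530876163
1003.0808468836,305.834004677858,305.834004677858
1075.1022158124,41.2105778973128,41.2105778973128
1077.1485284739,38.7997258317286,38.7997258317286
1091.1641495513,20.306866080309,20.306866080309
1119.1953900054,44.7801158721115,44.7801158721115
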