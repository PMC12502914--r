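"feature001","feature002","feature003","feature004","feature005","feature006"
-0.1647,-0.2609,1.1763,-0.4454,-0.0865,-0.638
-1.392,-1.5019,-1.7517,-1.1772,0.1457,0.8314
1.4658,1.1221,-0.7872,0.0678,-1.0775,-0.9554
0.0482,-0.5343,-0.315,-0.7732,0.6165,0.3674
1.9081,0.7536,1.1122,0.3838,-0.5954,-0.179
1.7309,-0.2053,-0.1122,-0.2998,0.1402,-1.5396
0.0581,-0.8031,-1.06,0.484,0.9139,0.7568
0.6453,0.4387,1.2376,2.6009,1.5058,2.0534
1.7256,-0.0024,2.0898,0.1192,-1.2913,-0.6575
-0.529,-0.387,-1.8896,0.706,0.3741,-0.4843
0.1664,0.2281,1.3902,2.5413,1.5605,1.9157
-0.2547,-0.2995,-0.561,-0.0801,0.8168,0.634
0.3328,-0.0858,0.8068,1.1802,1.0234,1.3899
0.1824,-1.4108,-2.2853,-2.6485,-0.8246,-0.2256
1.1646,0.3461,-0.0526,0.3797,1.1795,1.121
0.5935,-1.262,-1.4614,-1.2019,-1.2136,0.6454
-0.8918,0.5524,-0.1484,-0.2175,-0.6444,0.2477
0.5773,-0.5803,-1.2231,-0.1334,-0.0739,0.288
-0.8249,-0.2841,0.1779,0.9838,0.7854,-0.1916
-1.1573,-0.1287,0.989,0.4545,1.4444,1.2249
0.778,0.3937,-0.2308,2.1698,0.3355,-0.191
-1.2042,0.5644,0.085,0.5526,-0.4806,1.6481
0.3067,-0.5802,-1.2528,-0.8017,0.2697,0.4318
-0.8337,-0.0328,0.846,0.8054,0.0547,-0.6638
1.4181,-0.1372,0.418,0.1222,-0.1252,1.3586
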