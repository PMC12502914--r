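"y"
0.4586
-0.2294
-1.857
-0.2897
1.7671
-0.4427
-0.5889
-0.1206
1.6531
-0.8714
0.7807
-0.6139
-0.3276
-0.3552
0.7809
0.6087
1.0762
1.0656
2.1616
0.0705
-2.5352
-0.5413
-0.7759
-0.296
1.1514
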