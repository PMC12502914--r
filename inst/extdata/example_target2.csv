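"y"
0.4125
0.4982
0.3677
-0.5706
0.7388
-2.2683
0.614
0.4036
2.0516
0.2632
0.1104
1.1958
0.7333
-0.0045
-0.0212
0.1385
-1.0701
1.2361
-0.5398
-0.2962
0.6882
-0.399
-0.1035
1.5295
-0.6346
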