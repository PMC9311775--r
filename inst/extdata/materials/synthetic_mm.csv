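"strain","stress_kPa"
0,0
0.05,3.274807
0.1,4.700437
0.15,5.327667
0.2,5.618642
0.25,5.784065
0.3,5.933439
0.35,6.147636
0.4,6.525417
0.45,7.236144
0.5,8.617956
0.55,11.409282
0.6,17.374171
0.65,31.239117
0.7,67.868831
0.75,186.775139
0.8,747.100632
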