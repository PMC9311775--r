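"strain","stress_kPa"
0,0
0.05,9.35659
0.1,13.42982
0.15,15.221907
0.2,16.053264
0.25,16.525901
0.3,16.952682
0.35,17.564674
0.4,18.644047
0.45,20.674697
0.5,24.622731
0.55,32.597948
0.6,49.640487
0.65,89.254621
0.7,193.910946
0.75,533.643254
0.8,2134.573234
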