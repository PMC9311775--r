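"strain","stress_kPa"
0,0
0.05,1.559432
0.1,2.238303
0.15,2.536984
0.2,2.675544
0.25,2.754317
0.3,2.825447
0.35,2.927446
0.4,3.107341
0.45,3.445783
0.5,4.103788
0.55,5.432991
0.6,8.273415
0.65,14.87577
0.7,32.318491
0.75,88.940542
0.8,355.762206
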