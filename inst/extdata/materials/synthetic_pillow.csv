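"strain","stress_kPa"
0,0
0.05,3.438547
0.1,4.935459
0.15,5.594051
0.2,5.899574
0.25,6.073269
0.3,6.230111
0.35,6.455018
0.4,6.851687
0.45,7.597951
0.5,9.048854
0.55,11.979746
0.6,18.242879
0.65,32.801073
0.7,71.262273
0.75,196.113896
0.8,784.455663
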