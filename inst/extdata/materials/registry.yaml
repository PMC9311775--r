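# Synthetic material registry: curves are constructed (typical foam shape,
# ILD25-calibrated), not digitised measurements.
materials:
  SM:     {file: synthetic_sm.csv,     thickness_mm: 200, poisson: 0.01}
  MM:     {file: synthetic_mm.csv,     thickness_mm: 200, poisson: 0.01}
  HM:     {file: synthetic_hm.csv,     thickness_mm: 200, poisson: 0.01}
  pillow: {file: synthetic_pillow.csv, thickness_mm: 90,  poisson: 0.01}
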