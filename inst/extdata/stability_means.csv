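timepoint,temperature_c,humidity_pct,r_raw,g_raw,b_raw,c_raw
08:00,22.3,55.1,69.2,39.0,36.2,155.6
12:00,24.9,53.8,71.0,40.0,37.0,159.0
16:00,29.8,44.7,70.0,39.0,37.0,157.0
20:00,22.7,52.4,70.0,39.0,37.0,157.0
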