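sample_id,replicate,r_raw,g_raw,b_raw,c_raw
W1,1,27.9,27.0,18.8,80.9
W2,1,29.0,29.0,19.2,85.0
W3,1,25.8,23.8,18.0,74.0
M1,1,29.9,26.5,19.0,82.1
M2,1,30.9,27.9,20.9,86.3
M3,1,30.0,26.1,20.0,78.0
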