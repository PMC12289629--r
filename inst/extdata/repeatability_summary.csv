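sample_id,plant,channel,mean,sd,cv_percent
1,wheat,r_raw,27.9,0.0,0.000
1,wheat,g_raw,27.0,0.1,0.341
1,wheat,b_raw,18.8,0.1,0.382
1,wheat,c_raw,80.9,0.5,0.666
2,wheat,r_raw,29.0,0.0,0.000
2,wheat,g_raw,29.0,0.0,0.000
2,wheat,b_raw,19.2,0.4,2.083
2,wheat,c_raw,85.0,0.0,0.000
3,wheat,r_raw,25.8,0.0,0.000
3,wheat,g_raw,23.8,0.0,0.000
3,wheat,b_raw,18.0,0.0,0.000
3,wheat,c_raw,74.0,0.0,0.000
4,maize,r_raw,29.9,0.3,1.003
4,maize,g_raw,26.5,0.5,1.889
4,maize,b_raw,19.0,0.0,0.000
4,maize,c_raw,82.1,0.5,0.656
5,maize,r_raw,30.9,0.3,0.971
5,maize,g_raw,27.9,0.3,1.075
5,maize,b_raw,20.9,0.3,1.435
5,maize,c_raw,86.3,0.6,0.742
6,maize,r_raw,30.0,0.0,0.000
6,maize,g_raw,26.1,0.3,1.149
6,maize,b_raw,20.0,0.0,0.000
6,maize,c_raw,78.0,0.0,0.000
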