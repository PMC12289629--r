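crop,set,quantity,min,max,mean,sd,cv_percent
wheat,modeling,spad,33.0,65.5,49.3,7.185,14.57
wheat,modeling,cla_mg_g,1.054,3.442,2.140,0.614,28.68
wheat,modeling,clb_mg_g,0.272,1.016,0.571,0.183,32.12
wheat,modeling,tcl_mg_g,1.340,4.415,2.711,0.795,29.32
wheat,validation,spad,32.9,61.3,47.3,7.570,16.00
wheat,validation,cla_mg_g,0.840,3.766,1.977,0.710,35.92
wheat,validation,clb_mg_g,0.212,1.093,0.523,0.207,39.49
wheat,validation,tcl_mg_g,1.052,4.859,2.499,0.915,36.62
maize,modeling,spad,22.8,54.2,37.1,6.605,17.82
maize,modeling,cla_mg_g,1.125,2.640,1.828,0.406,22.23
maize,modeling,clb_mg_g,0.217,0.524,0.370,0.084,22.66
maize,modeling,tcl_mg_g,1.342,3.161,2.198,0.488,22.20
maize,validation,spad,23.4,58.8,39.8,7.515,18.88
maize,validation,cla_mg_g,1.088,2.695,1.907,0.439,23.03
maize,validation,clb_mg_g,0.235,0.526,0.385,0.085,22.07
maize,validation,tcl_mg_g,1.329,3.220,2.293,0.523,22.80
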