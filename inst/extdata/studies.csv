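"id","label","events_trt","n_trt","events_ctl","n_ctl","y","se","included"
"S1","Study 1",10,1474,6,842,,,TRUE
"S2","Study 2",8,2873,7,539,,,TRUE
"S3","Study 3",16,2877,16,1036,,,TRUE
"S4","Study 4",5,1053,35,2922,,,TRUE
"S5","Study 5",7,1945,9,747,,,TRUE
"S6","Study 6",2,2658,10,1721,,,TRUE
"S7","Study 7",16,2447,45,2925,,,TRUE
"S8","Study 8",11,2029,33,2586,,,TRUE
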