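stratum,device,placement,b0,b0_lo,b0_hi,b1,b1_lo,b1_hi,cp3,cp3_lo,cp3_hi,cp6,cp6_lo,cp6_hi,cp9,cp9_lo,cp9_hi
GT3X_hip,GT3X,hip,1.062,1.019,1.105,0.0199,0.0193,0.0206,1132,1041,1223,4853,4688,5018,9468,9135,9800
ACTT_hip,ACTT,hip,1.107,1.066,1.148,0.0088,0.0085,0.0091,5057,4624,5491,23339,22522,24157,46410,44764,48055
ACTT_wrist,ACTT,wrist,1.233,1.195,1.271,0.0081,0.0079,0.0084,3761,3357,4165,22368,21503,23232,47203,45409,48997
GT3X_wrist,GT3X,wrist,1.207,1.168,1.245,0.0127,0.0123,0.0132,1698,1525,1871,9503,9143,9862,19787,19047,20527
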