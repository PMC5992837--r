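category,period,rate
retinopathy,period1,0.27
retinopathy,period2,0.29
retinopathy,period3,0.30
retinopathy,period4,0.30
cataract,period1,1.98
cataract,period2,2.08
cataract,period3,2.19
cataract,period4,2.23
nephropathy,period1,0.47
nephropathy,period2,0.67
nephropathy,period3,0.74
nephropathy,period4,0.75
cardiovascular,period1,2.49
cardiovascular,period2,2.84
cardiovascular,period3,2.90
cardiovascular,period4,2.76
foot_lesions,period1,0.40
foot_lesions,period2,0.53
foot_lesions,period3,0.62
foot_lesions,period4,0.68
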