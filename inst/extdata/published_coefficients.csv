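outcome,group,method,b0,b1,b2,b3,b4,b5,b6,ar1,dw
cost_total,overall,AR1,29.982,0.295,-0.984,-0.136,-4.384,0.192,-2.643,0.282,1.98
cost_total,reduced,AR1,23.738,0.065,1.357,-0.185,-4.809,-0.023,-1.858,0.277,2.06
cost_total,constant,AR1,6.240,0.229,-2.264,0.049,0.384,0.211,-0.856,-0.080,1.80
ddd_total,overall,AR1,79.447,0.463,-0.556,-0.023,-1.058,-0.114,-6.344,0.338,2.12
ddd_total,reduced,AR1,70.638,0.161,1.321,-0.119,-1.442,-0.340,-5.002,0.333,2.14
ddd_total,constant,OLS,8.794,0.301,-1.792,0.094,0.426,0.220,-1.370,NA,1.99
n_patients,overall,OLS,1408058,11758,-47643,1698,17535,-2504,-89533,NA,1.95
n_patients,reduced,OLS,1129486,4909,-6604,532,7296,-7523,-64306,NA,2.07
n_patients,constant,AR1,278489,6820,-39690,1207,8751,4989,-26186,-0.168,1.79
cost_per_patient,overall,OLS,43492,160,-2149,-163,-3380,107,-1063,NA,1.86
cost_per_patient,reduced,OLS,20992,-30,1123,-145,-3670,81,-550,NA,1.96
cost_per_patient,constant,AR1,22455,183,-2800,-27,233,43,-499,-0.485,2.12
ddd_per_patient,overall,AR1,94.160,0.095,0.317,-0.083,-1.564,-0.010,-2.610,0.224,2.12
ddd_per_patient,reduced,AR1,62.535,-0.120,1.330,-0.090,-1.416,0.056,-1.384,0.135,2.04
ddd_per_patient,constant,OLS,31.594,0.215,-0.934,-0.0004,0.005,-0.068,-1.123,NA,2.08
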