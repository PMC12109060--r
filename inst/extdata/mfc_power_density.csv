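extract,condition_id,pd_mean,pd_sd,published_amplification,published_amplification_sd
OTL-W,blank1,9.882,0.494,1.00,0.10
OTL-W,250ppm,16.349,1.138,1.65,0.20
OTL-W,500ppm,18.946,1.741,1.92,0.27
OTL-W,750ppm,20.129,1.507,2.04,0.25
OTL-W,1000ppm,21.369,1.875,2.16,0.30
OTL-W,1500ppm,22.166,2.026,2.24,0.32
OTL-W,2000ppm,24.374,4.113,2.47,0.54
OTL-W,blank2,12.070,0.506,1.22,0.11
OTL-W,dopamine,33.531,2.089,3.39,0.38
OTL-E,blank1,11.193,0.798,1.00,0.1411
OTL-E,250ppm,23.500,4.757,2.10,0.57
OTL-E,500ppm,22.158,4.717,1.98,0.56
OTL-E,750ppm,17.459,2.446,1.56,0.33
OTL-E,1000ppm,16.001,2.385,1.43,0.31
OTL-E,1500ppm,15.091,2.024,1.35,0.28
OTL-E,2000ppm,14.376,1.963,1.28,0.27
OTL-E,blank2,9.929,0.762,0.89,0.13
OTL-E,dopamine,29.407,2.975,2.63,0.45
OTS-W,blank1,7.604,0.471,1.00,0.12
OTS-W,250ppm,8.477,1.509,1.11,0.27
OTS-W,500ppm,9.404,1.414,1.24,0.26
OTS-W,750ppm,10.617,1.426,1.40,0.27
OTS-W,blank2,7.488,0.309,0.98,0.10
OTS-W,dopamine,24.496,2.323,3.22,0.51
OTS-E,blank1,7.150,0.365,1.00,0.10
OTS-E,250ppm,11.636,1.509,1.63,0.29
OTS-E,500ppm,12.363,1.414,1.73,0.29
OTS-E,750ppm,12.874,1.426,1.80,0.29
OTS-E,1000ppm,13.614,1.475,1.90,0.30
OTS-E,1500ppm,14.961,1.446,2.09,0.31
OTS-E,dopamine,20.473,1.661,2.86,0.38
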