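preset,p_correct,b0,b1,sigma,lapse_rate,alpha,beta,rl_rt_s
subject_1,0.875,0.905,0.072,0.15,0.02,0.45,6.0,1.0
subject_2,0.902,0.879,0.057,0.15,0.02,0.32,5.0,1.0
subject_3,0.812,0.770,0.049,0.15,0.03,0.33,4.5,1.0
subject_4,0.850,0.850,0.060,0.15,0.02,0.25,4.0,1.0
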