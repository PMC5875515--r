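plaque_type,mean_factor,sd_factor,cv_pct,n
COMS10,0.264,0.007,2.6,8
COMS12,0.256,0.007,2.6,6
COMS12N,0.252,0.006,2.4,6
COMS14,0.264,0.008,3.2,5
COMS14N,0.254,0.010,4.1,9
COMS16,0.262,0.010,3.8,2
COMS16N,0.245,0.007,2.7,4
COMS18,0.250,0.004,1.5,3
COMS18N,0.254,0.008,3.3,2
COMS20,0.234,0.004,1.9,11
COMS20N,0.243,0.005,2.0,3
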