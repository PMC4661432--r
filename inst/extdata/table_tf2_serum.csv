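patient,k21,k12,kel,vol_per_m2,vc,clearance
1,0.033,0.0062,0.194,2,4.01,0.78
2,0.033,0.008,0.177,1.82,2.71,0.48
3,0.036,0.0081,0.169,1.83,4.93,0.84
4,0.036,0.0071,0.182,1.8,3.33,0.61
5,0.034,0.0075,0.183,1.81,3.05,0.56
6,0.033,0.0085,0.174,1.84,3.2,0.56
7,0.035,0.0068,0.183,1.92,3.73,0.68
8,0.035,0.0073,0.177,1.77,3.45,0.61
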