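patient,isotope,k21,k12,A,B,mr,kel,vol_per_m2,vc,clearance
1,In111,0.027,0.021,1.35,0.169,124.2,0.226,6.69,13.4,3.04
1,Lu177,0.024,0.021,1.37,0.172,125.5,0.241,6.5,13.1,3.15
2,In111,0.026,0.023,1.31,0.167,40.7,0.25,6.54,9.7,2.43
2,Lu177,0.027,0.022,1.22,0.156,40.1,0.219,6.63,9.9,2.16
3,In111,0.028,0.015,1.53,0.199,35.7,0.185,6.23,16.8,3.11
3,Lu177,0.028,0.017,1.43,0.183,37.8,0.165,6.25,16.8,2.78
4,In111,0.026,0.026,0.92,0.141,22.6,0.112,6.9,12.7,1.43
4,Lu177,0.029,0.019,1.29,0.167,22,0.173,6.78,12.5,2.17
5,In111,0.027,0.017,1.53,0.196,22.5,0.235,6.15,12,2.82
5,Lu177,0.028,0.017,1.52,0.196,31.1,0.249,6.13,11.9,2.97
6,In111,0.027,0.019,1.41,0.179,109,0.291,6.44,11.2,3.25
6,Lu177,0.028,0.021,1.31,0.17,18.8,0.179,6.93,12,2.15
7,In111,0.027,0.022,1.41,0.181,3.3,0.146,6.21,12,1.76
7,Lu177,0.028,0.018,1.41,0.181,3.2,0.137,6.54,12.7,1.74
8,In111,0.028,0.018,1.44,0.182,2.3,0.161,6.18,10.4,1.68
8,Lu177,0.028,0.02,1.16,0.174,2.5,0.124,6.49,10.9,1.36
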