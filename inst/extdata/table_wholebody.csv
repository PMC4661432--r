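patient,isotope,k21,k12,A,B,mr,kel
1,In111,0.0152,0.0101,0.097,0.13,124.2,0.18
1,Lu177,0.0177,0.0094,0.11,0.15,125.5,0.23
2,In111,0.0126,0.01,0.104,0.14,40.7,0.18
2,Lu177,0.0138,0.0101,0.115,0.16,40.1,0.21
3,In111,0.0178,0.009,0.115,0.16,35.7,0.2
3,Lu177,0.0197,0.0085,0.121,0.17,37.8,0.23
4,In111,0.0136,0.0099,0.097,0.14,22.6,0.15
4,Lu177,0.0166,0.0099,0.089,0.13,22,0.13
5,In111,0.0146,0.0104,0.098,0.14,22.5,0.15
5,Lu177,0.0165,0.0102,0.083,0.12,31.1,0.13
6,In111,0.0141,0.0101,0.071,0.11,109,0.12
6,Lu177,0.0166,0.0098,0.091,0.13,18.8,0.13
7,In111,0.0143,0.0101,0.102,0.14,3.3,0.12
7,Lu177,0.0191,0.009,0.07,0.13,3.2,0.08
8,In111,0.0141,0.01,0.11,0.15,2.3,0.12
8,Lu177,0.019,0.009,0.098,0.14,2.5,0.11
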