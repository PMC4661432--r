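organ,k_on,k_on_sd,k_off,k_off_sd,fraction,fraction_sd
lung,0.00106,6e-05,0.0117,6e-04,0.0338,0.0019
liver,0.00145,0.00011,0.0114,8e-04,0.0233,0.0021
kidneys,0.00435,0.00028,0.0222,8e-04,0.0591,0.0037
spleen,0.00148,0.00011,0.013,8e-04,0.0221,0.0019
heart,0.00045,4e-05,0.0094,9e-04,0.0308,0.0021
aorta,0.00061,5e-05,0.0104,9e-04,0.0366,0.0026
tumor,NA,NA,NA,NA,0.027,0.0026
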