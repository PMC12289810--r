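{"schema":"flatmetric/calibration/1","location":3.24928717625662,"scale":1.60948182608482,"amplitude":[3.11912936423373,4.66184928456481,4.8118957602471,4.77465380552523,4.95630177231096],"offset":[0.0693372213746048,0.0904881856706033,0.0903992708013364,0.0905887982994753,0.091667082740496],"dims_fitted":[2,5,10,15,20],"fit_rmse":0.0136511220163676}
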