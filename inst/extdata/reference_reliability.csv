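plane,part,mean,sd,alpha,icc
frontal,left_leg,-0.12,3.33,0.95,0.87
frontal,right_leg,0.73,4.64,0.96,0.90
frontal,pelvis,0.02,1.18,0.88,0.71
sagittal,left_leg,7.56,3.46,0.97,0.92
sagittal,right_leg,7.26,3.38,0.97,0.90
sagittal,pelvis,21.51,7.94,0.99,0.98
transverse,left_leg,-1.62,9.56,0.80,0.57
transverse,right_leg,1.59,7.16,0.81,0.59
transverse,pelvis,0.01,0.21,0.99,0.99
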