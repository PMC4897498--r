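item,alpha_hat,alpha_mcse,beta_hat,beta_mcse,ratio
1,0.4280,0.0013,-0.5273,0.0009,-1.2320
2,0.2993,0.0005,-0.5884,0.0004,-1.9659
3,0.3316,0.0002,-1.0379,0.0003,-3.1300
4,0.3061,0.0015,-1.2878,0.0008,-4.2071
5,0.3952,0.0009,-1.1658,0.0014,-2.9499
6,0.7231,0.0018,-0.8883,0.0013,-1.2285
7,0.3302,0.0006,-0.4362,0.0006,-1.3210
8,0.4612,0.0009,-1.1996,0.0008,-2.6010
9,0.4669,0.0007,-0.1065,0.0005,-0.2281
10,0.4943,0.0008,-0.0358,0.0008,-0.0724
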