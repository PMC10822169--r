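subject,sex,age,height_m,bmi
S1,Female,22,1.59,23.73
S2,Female,25,1.68,21.26
S3,Male,24,1.75,29.39
S4,Female,22,1.62,20.19
S5,Female,26,1.68,19.49
S6,Male,28,1.80,24.69
S7,Male,28,1.92,24.41
S8,Male,27,1.75,27.75
S9,Female,23,1.65,22.04
S10,Male,22,1.75,21.22
S11,Female,22,1.75,26.12
S12,Male,28,1.70,25.95
S13,Female,23,1.60,21.48
S14,Female,26,1.65,22.04
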