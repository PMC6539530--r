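feature,condition,mean,sd
nLAP,S1,15.29,4.19
nLAP,R1,12.22,3.64
nLAP,S2,14.14,3.53
nLAP,R2,13.21,3.22
nRAP,S1,14.11,3.63
nRAP,R1,11.85,3.60
nRAP,S2,12.88,3.00
nRAP,R2,12.47,3.16
nLBP,S1,27.37,9.11
nLBP,R1,21.62,9.09
nLBP,S2,22.61,7.63
nLBP,R2,20.42,8.53
nRBP,S1,25.60,9.83
nRBP,R1,20.88,8.42
nRBP,S2,21.43,7.71
nRBP,R2,19.50,9.47
DPA,S1,2.32,4.52
DPA,R1,0.65,2.01
DPA,S2,1.78,4.63
DPA,R2,1.16,2.88
TPA,S1,-0.81,3.84
TPA,R1,0.76,3.47
TPA,S2,-1.80,2.85
TPA,R2,0.59,2.55
APA,S1,-5.87,2.33
APA,R1,-2.05,1.51
APA,S2,-6.16,2.14
APA,R2,-3.11,1.90
BPA,S1,-5.95,6.76
BPA,R1,-2.07,4.37
BPA,S2,-4.66,5.40
BPA,R2,-3.44,4.31
mRR,S1,733.16,109.41
mRR,R1,719.31,116.85
mRR,S2,712.37,97.87
mRR,R2,735.24,100.15
SDRR,S1,74.74,58.37
SDRR,R1,77.48,38.97
SDRR,S2,68.93,49.41
SDRR,R2,75.20,47.89
RMSSD,S1,66.36,54.69
RMSSD,R1,72.48,36.27
RMSSD,S2,63.94,47.09
RMSSD,R2,69.77,43.25
nLF_HRV,S1,10.89,3.35
nLF_HRV,R1,10.03,2.88
nLF_HRV,S2,10.38,2.25
nLF_HRV,R2,9.59,1.92
nHF_HRV,S1,11.63,4.59
nHF_HRV,R1,13.71,6.51
nHF_HRV,S2,10.20,3.29
nHF_HRV,R2,13.72,6.16
LF_HF,S1,97.15,14.26
LF_HF,R1,79.04,16.68
LF_HF,S2,105.93,18.34
LF_HF,R2,76.95,18.72
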