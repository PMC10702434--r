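congener,class,carbons,air_mean,air_se,air_lo,air_hi,sw_mean,sw_se,sw_lo,sw_hi,sed_mean,sed_se,sed_lo,sed_hi,ai_mean,ai_se,ai_lo,ai_hi,ti_mean,ti_se,ti_lo,ti_hi,gi_mean,gi_se,gi_lo,gi_hi,liver_mean,liver_se,liver_lo,liver_hi,note
Sigma46PFAS,total,,1.02,0.07,0.77,1.63,0.14,0.02,0.08,0.43,15.66,2.5,3.16,35.5,13.30,1.14,7.35,21.83,2.47,0.10,2.15,3.35,23.1,0.30,17.7,32.1,67.9,2.03,31.4,132.3,
PFBA,PFCA,4,0.06,0.008,0.04,0.08,0.01,0.001,0.01,0.01,ND,,,,ND,,,,ND,,,,ND,,,,ND,,,,
PFPeA,PFCA,5,ND,,,,0.01,0.001,0.01,0.01,ND,,,,0.20,0.001,0.19,0.22,ND,,,,ND,,,,ND,,,,
PFHxA,PFCA,6,0.03,0.01,0.006,0.08,0.02,0.001,0.02,0.02,0.92,0.25,0.36,1.71,0.23,0.04,0.16,0.36,ND,,,,ND,,,,ND,,,,
PFHpA,PFCA,7,0.002,0.001,0.001,0.004,0.004,0.001,0.003,0.004,ND,,,,ND,,,,ND,,,,ND,,,,ND,,,,
PFOA,PFCA,8,0.007,0.001,0.005,0.01,0.006,0.001,0.006,0.006,0.29,0.10,0.11,0.53,0.10,0.001,0.10,0.11,ND,,,,0.12,0.001,0.10,0.15,ND,,,,
PFNA,PFCA,9,0.001,0.001,0.001,0.002,0.001,0.001,0.001,0.001,ND,,,,ND,,,,ND,,,,0.37,0.02,0.12,0.61,1.34,0.07,1.02,1.54,
PFDA,PFCA,10,0.002,0.001,0.002,0.004,0.001,0.001,0.001,0.002,0.44,0.11,0.13,0.76,0.1,0.001,0.10,0.10,ND,,,,0.82,0.06,0.44,1.35,2.7,0.15,1.78,4.09,
PFUnA,PFCA,11,ND,,,,ND,,,,ND,,,,ND,,,,ND,,,,0.35,0.02,0.25,0.49,0.87,0.04,0.72,1.23,
PFDoA,PFCA,12,ND,,,,ND,,,,0.65,0.15,0.21,1.02,0.40,0.02,0.35,0.46,ND,,,,0.19,0.01,0.14,0.25,ND,,,,
PFTrDA,PFCA,13,0.002,0.001,0.002,0.002,ND,,,,0.28,0.07,0.10,0.49,0.24,0.001,0.22,0.26,ND,,,,0.17,0.001,0.12,0.24,ND,,,,
PFTeDA,PFCA,14,ND,,,,ND,,,,0.47,0.13,0.13,0.91,0.27,0.04,0.20,0.42,ND,,,,0.18,0.01,0.14,0.32,ND,,,,
PFBS,PFSA,4,0.004,0.001,0.002,0.005,0.004,0.001,0.003,0.004,ND,,,,ND,,,,ND,,,,ND,,,,ND,,,,
PFPeS,PFSA,5,X,,,,0.0005,0.001,0.0004,0.0005,ND,,,,ND,,,,ND,,,,ND,,,,ND,,,,
PFHxS,PFSA,6,0.001,0.001,0.0007,0.003,0.002,0.001,0.002,0.002,ND,,,,ND,,,,ND,,,,ND,,,,ND,,,,air range low printed with a dropped minus exponent (7.0e4); corrected to 7.0e-4
PFOS,PFSA,8,0.10,0.04,0.03,0.26,0.006,0.001,0.005,0.007,1.99,0.57,0.51,4.4,1.46,0.07,1.28,1.57,2.08,0.19,1.90,2.83,9.6,0.58,6.0,14.9,29.18,1.68,21.8,49.1,
PFDS,PFSA,10,ND,,,,ND,,,,0.51,0.09,0.25,0.56,0.12,0.001,0.11,0.12,ND,,,,0.17,0.001,0.12,0.21,ND,,,,
6:2 FTS,FTS,6,0.003,0.001,0.003,0.005,0.006,0.001,0.006,0.006,ND,,,,ND,,,,0.41,0.04,0.36,0.52,ND,,,,ND,,,,
8:2 FTS,FTS,8,0.001,0.001,0.0002,0.0003,ND,,,,ND,,,,ND,,,,ND,,,,ND,,,,ND,,,,air mean exceeds printed range upper bound; stored as printed
10:2 FTS,FTS,10,0.002,0.001,0.0001,0.001,X,,,,X,,,,X,,,,X,,,,X,,,,X,,,,air range low printed with a dropped minus exponent (1.0e4); corrected to 1.0e-4
6:2 FTOH,FTOH,6,0.33,0.05,0.24,0.51,X,,,,X,,,,X,,,,X,,,,X,,,,X,,,,
8:2 FTOH,FTOH,8,0.28,0.04,0.20,0.43,X,,,,X,,,,X,,,,X,,,,X,,,,X,,,,
10:2 FTOH,FTOH,10,0.19,0.02,0.13,0.24,X,,,,X,,,,X,,,,X,,,,X,,,,X,,,,
5:3 FTCA,FTCA,5,X,,,,ND,,,,ND,,,,7.59,2.23,3.82,15.9,ND,,,,4.06,0.31,2.25,5.85,ND,,,,
7:3 FTCA,FTCA,7,X,,,,ND,,,,ND,,,,ND,,,,ND,,,,4.57,0.35,2.24,8.03,24.68,3.13,11.8,43.1,
PFOSA,FOSA,8,X,,,,ND,,,,0.35,0.10,0.11,0.61,0.33,0.03,0.26,0.43,ND,,,,0.13,0.001,0.10,0.15,ND,,,,
N-MeFOSA,FOSA,8,0.002,0.001,0.001,0.004,ND,,,,ND,,,,ND,,,,ND,,,,0.65,0.09,0.15,1.46,ND,,,,
N-EtFOSA,FOSA,8,0.002,0.001,0.001,0.003,ND,,,,ND,,,,ND,,,,ND,,,,0.44,0.05,0.21,0.80,ND,,,,
N-MeFOSAA,FOSAA,8,X,,,,0.06,0.06,0.0005,0.36,2.05,0.20,0.55,1.7,0.48,0.10,0.25,0.81,ND,,,,0.30,0.01,0.23,0.42,0.74,0.04,0.57,0.96,sediment mean exceeds printed range upper bound; stored as printed
N-EtFOSAA,FOSAA,8,X,,,,0.0007,0.001,0.0005,0.0008,1.66,0.37,0.65,3.22,0.78,0.24,0.34,1.67,ND,,,,0.32,0.02,0.19,0.47,0.79,0.05,0.61,0.96,
N-MeFOSE,FOSE,8,0.009,0.002,0.006,0.02,ND,,,,ND,,,,ND,,,,ND,,,,ND,,,,ND,,,,
N-EtFOSE,FOSE,8,0.005,0.002,0.004,0.006,ND,,,,ND,,,,ND,,,,ND,,,,3.11,1.27,0.63,2.81,ND,,,,GI mean exceeds printed range upper bound; stored as printed
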