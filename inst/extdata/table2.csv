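factor_kind,numerator,denominator,PFPeA,PFHxA,PFOA,PFNA,PFDA,PFDoA,PFTrDA,PFOS,PFDS,6:2 FTS,5:3 FTCA,PFOSA,N-MeFOSA,N-EtFOSA,N-MeFOSAA,N-EtFOSAA,N-EtFOSE
BAF,aquatic_invertebrates,surface_water,20.1,11.5,16.7,-,100,-,-,243,-,-,-,-,-,-,7.98,1114,-
BAF,aquatic_invertebrates,sediment,-,0.25,0.34,-,-,0.62,0.86,0.73,0.24,-,-,0.94,-,-,0.23,0.47,-
BAF,gi_tract,surface_water,-,-,-,370,820,-,-,1600,-,-,-,-,-,-,5.11,457,-
BAF,liver,surface_water,-,-,-,1340,-,-,-,4863,-,-,-,-,-,-,12.3,1128,-
BAF,terrestrial_invertebrates,air,-,-,-,-,-,-,-,20.8,-,137,-,-,-,-,-,-,-
BAF,gi_tract,air,-,-,-,370,410,-,85.2,95.8,-,-,-,-,325,220,-,-,622
BAF,liver,air,-,-,-,1340,1350,-,-,292,-,-,-,-,-,-,-,-,-
BMF,gi_tract,aquatic_invertebrates,-,-,-,-,8.21,0.48,0.71,6.58,1.42,-,0.53,0.39,-,-,0.63,0.41,-
BMF,liver,aquatic_invertebrates,-,-,-,-,27.3,-,-,19.9,-,-,-,-,-,-,1.54,1.01,-
BMF,gi_tract,terrestrial_invertebrates,-,-,-,-,-,-,-,4.62,-,-,-,-,-,-,-,-,-
BMF,liver,terrestrial_invertebrates,-,-,-,-,-,-,-,14.0,-,-,-,-,-,-,-,-,-
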