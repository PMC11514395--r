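strategy,gene,class,carrier,p_response,p_relapse_given_response,p_side_effect
PGX,CYP2D6,PM,CARRIER,0.370,0.099,0.490
PGX,CYP2D6,IM,CARRIER,0.370,0.099,0.490
PGX,CYP2D6,URM,CARRIER,0.350,0.099,0.300
PGX,CYP2D6,PM,NONCARRIER,0.370,0.099,0.490
PGX,CYP2D6,IM,NONCARRIER,0.370,0.099,0.490
PGX,CYP2D6,URM,NONCARRIER,0.350,0.099,0.300
PGX,CYP2D6,NORMAL,NONCARRIER,0.370,0.099,0.300
SOC,CYP2D6,PM,CARRIER,0.370,0.233,0.900
SOC,CYP2D6,IM,CARRIER,0.370,0.233,0.700
SOC,CYP2D6,URM,CARRIER,0.350,0.233,0.300
SOC,CYP2D6,PM,NONCARRIER,0.370,0.233,0.900
SOC,CYP2D6,IM,NONCARRIER,0.370,0.233,0.700
SOC,CYP2D6,URM,NONCARRIER,0.350,0.233,0.300
SOC,CYP2D6,NORMAL,NONCARRIER,0.370,0.233,0.300
PGX,CYP2C19,PM,CARRIER,0.580,0.099,0.490
PGX,CYP2C19,IM,CARRIER,0.480,0.099,0.490
PGX,CYP2C19,URM,CARRIER,0.370,0.099,0.490
PGX,CYP2C19,RM,CARRIER,0.370,0.099,0.490
PGX,CYP2C19,PM,NONCARRIER,0.580,0.099,0.490
PGX,CYP2C19,IM,NONCARRIER,0.480,0.099,0.490
PGX,CYP2C19,URM,NONCARRIER,0.370,0.099,0.490
PGX,CYP2C19,RM,NONCARRIER,0.370,0.099,0.490
PGX,CYP2C19,NORMAL,NONCARRIER,0.370,0.099,0.490
SOC,CYP2C19,PM,CARRIER,0.480,0.230,0.550
SOC,CYP2C19,IM,CARRIER,0.370,0.230,0.510
SOC,CYP2C19,URM,CARRIER,0.370,0.230,0.490
SOC,CYP2C19,RM,CARRIER,0.370,0.230,0.900
SOC,CYP2C19,PM,NONCARRIER,0.480,0.230,0.550
SOC,CYP2C19,IM,NONCARRIER,0.370,0.230,0.510
SOC,CYP2C19,URM,NONCARRIER,0.370,0.230,0.490
SOC,CYP2C19,RM,NONCARRIER,0.370,0.230,0.490
SOC,CYP2C19,NORMAL,NONCARRIER,0.370,0.230,0.490
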