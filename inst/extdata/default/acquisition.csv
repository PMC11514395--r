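strategy,gene,class,first_line,increased_dose,discontinuation
SOC,CYP2D6,PM,25,47,6
SOC,CYP2D6,IM,25,47,6
SOC,CYP2D6,URM,25,47,6
SOC,CYP2D6,NORMAL,25,47,6
PGX,CYP2D6,PM,12,25,6
PGX,CYP2D6,IM,12,25,6
PGX,CYP2D6,URM,24,47,6
PGX,CYP2D6,NORMAL,25,47,6
SOC,CYP2C19,PM,76,152,38
SOC,CYP2C19,IM,76,152,38
SOC,CYP2C19,URM,76,152,38
SOC,CYP2C19,RM,76,152,38
SOC,CYP2C19,NORMAL,76,152,38
PGX,CYP2C19,PM,38,108,19
PGX,CYP2C19,IM,38,108,19
PGX,CYP2C19,URM,76,152,38
PGX,CYP2C19,RM,76,152,38
PGX,CYP2C19,NORMAL,76,152,38
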