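strategy,response_return,relapse_onset,relapse_remission,no_response_onset,suicide_death,nonsuicide_death
PGX,0.1180,0.0949,0.0229,0.0965,0.1175,0.1180
SOC,0.1170,0.2062,0.0572,0.0965,0.1176,0.1170
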