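strategy,p_switch,p_titrate,p_observe,p_discontinue,p_suicide_attempt,p_suicide_death_given_attempt
PGX,0.680,0.200,0.250,0.260,0.060,0.006
SOC,0.450,0.240,0.250,0.080,0.060,0.006
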