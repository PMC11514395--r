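item,value
acquisition_PGX,648
acquisition_SOC,595
lab_screening,560
follow_up,500
relapse_event,1908
suicide_death_event,29
suicide_attempt_event,779
nonsuicide_death_event,2040
survival_event,2600
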