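item,value
lab_screening,560
consultation,1000
genotyping_panel,540
side_effect_management,841
relapse_event,954
suicide_death_event,15
suicide_attempt_event,390
nonsuicide_death_event,1020
survival_event,1300
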