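state,age_min,age_max,utility
response,40,49,0.871
response,50,59,0.842
response,60,69,0.823
response,70,79,0.790
response,80,200,0.736
relapse,,,0.55
no_response,,,0.48
suicide_attempt,,,0
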