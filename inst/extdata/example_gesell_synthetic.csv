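id,domain,milestone_months,n_passed,ca_months
ASD001,GM,48,2,60
ASD001,GM,54,2,60
ASD001,FM,42,3,60
ASD001,FM,48,1,60
ASD002,GM,36,2,55
ASD002,GM,42,4,55
ASD002,FM,48,2,55
ASD002,FM,54,3,55
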