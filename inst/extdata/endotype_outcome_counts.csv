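endotype,alive,expired,intervention,no_intervention,printed_survival_rate,printed_intervention_rate
HFA,52,135,51,136,27.8,27.3
HE,984,270,269,985,78.5,21.5
RFH,55,81,18,118,40.4,13.2
AA,124,53,41,136,70.1,23.2
HTN,450,425,225,650,51.4,25.7
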