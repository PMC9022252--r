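drug	gene
drugA	G0001
drugA	G0002
drugA	G0015
drugB	G0041
drugB	G0042
drugB	G0055
drugC	G0081
drugC	G0082
drugD	G0121
drugD	G0122
drugD	G0135
drugE	G0190
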