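t_stage,ln_negative,ln_positive
T1,98,18
T2,25,35
T3,48,128
T4,22,187
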