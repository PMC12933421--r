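# Per-framing evacuation compliance targets (proportions) used to calibrate
# the shipped decision weights.
control: 0.009
fear: 0.009
efficacy: 0.012
norm: 0.009
fear_efficacy: 0.123
fear_efficacy_norm: 0.154
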