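# M-phase-exit scenario: PP2A-B55 alone consumes its pEndos inhibitor
scenario: pp2a_only
horizon_s: 600
plot: false
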