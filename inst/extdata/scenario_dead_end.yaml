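# Counterfactual: pEndos as pure dead-end inhibitor (Kd 0.12 nM),
# destroyed only by PPX (250 nM, Km 85 uM, kcat 22.5 /s)
scenario: dead_end
horizon_s: 20000
plot: false
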