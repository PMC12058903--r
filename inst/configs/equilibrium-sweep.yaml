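# analytic equilibrium and critical-gradient tables (no PDE run)
scenario: equilibrium
params: {A: 4}
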