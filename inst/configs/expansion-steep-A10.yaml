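# 1D range expansion in a steep gradient with strong optimal dispersal
scenario: expansion
gradient: 1.5
params: {A: 10}
grid: {a: -50, b: 50, nx: 400}
solver: {t_end: 40, record_every: 1}
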