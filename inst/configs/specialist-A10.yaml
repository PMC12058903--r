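# specialist population (small utilisation variance) in a typical gradient
scenario: expansion
gradient: 0.2
params: {A: 10, V: 1}
grid: {a: -50, b: 50, nx: 400}
solver: {t_end: 30, record_every: 1}
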