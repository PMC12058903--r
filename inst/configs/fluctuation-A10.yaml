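# abrupt periodic optimum shifts, strong optimal dispersal
scenario: fluctuation
gradient: 1.5
params: {A: 10}
grid: {a: -50, b: 50, nx: 400}
schedule: {period: 2, amplitude: 5}
solver: {t_end: 16, record_every: 0.25}
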