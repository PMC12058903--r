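# high-amplitude fluctuations driving a moderately dispersing species down
scenario: fluctuation
gradient: 1.5
params: {A: 4}
schedule: {period: 2, amplitude: 9}
grid: {a: -50, b: 50, nx: 400}
solver: {t_end: 40, record_every: 0.5}
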