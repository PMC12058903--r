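# 2D fragmented habitat, strong optimal dispersal
scenario: fragmented
gradient: 1
params: {A: 10}
grid: {nx: 200}
seed: 1
solver: {t_end: 40, record_every: 10}
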