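[substrate]
dims = 130 300 112.5
grid = 4 10 3

[cell_type granule]
count = 1
soma_radius = 5
rule_entry = granule
soma_positions = 65 50 56.25

[run]
steps = 120
seed = 1
synapse_max_distance = 2
resolution_attempts = 10
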