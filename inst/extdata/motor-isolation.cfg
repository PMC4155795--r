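[substrate]
dims = 1400 1400 1400
grid = 15 15 15

[cell_type motor]
count = 1
soma_radius = 25
rule_entry = motor
soma_positions = 700 700 700

[run]
steps = 300
seed = 1
synapse_max_distance = 2
resolution_attempts = 10
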