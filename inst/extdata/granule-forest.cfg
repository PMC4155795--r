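[substrate]
dims = 1300 300 225
grid = 43 10 7

[cell_type granule]
count = 100
soma_radius = 5
rule_entry = granule
soma_box = 20 30 15 1280 60 210

[run]
steps = 120
seed = 1
synapse_max_distance = 2
resolution_attempts = 10
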