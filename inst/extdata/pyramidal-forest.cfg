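[substrate]
dims = 6000 1800 1400
grid = 82 24 19

[layers]
depth_axis = z
L1 = 1300 1400
L2 = 1150 1300
L3 = 1000 1150
L4 = 850 1000
L5 = 0 850

[cell_type pyramidal]
count = 100
soma_radius = 10
rule_entry = pyramidal_soma
soma_box = 150 150 790 5850 1650 850

[run]
steps = 250
seed = 1
synapse_max_distance = 2
resolution_attempts = 10
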