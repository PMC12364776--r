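# Collimated 3-beam IMPT with shoot-through layers
target: CTV_small
spacing: 0.5
n_directions: 3
angles: [0, 120, 240]
shoot_through: true
collimated: true
prescription: 60
fractions: 30
initial_layers_per_direction: 24
final_layers: 72
falloff_weight_factor: 1
seed: 17
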