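'n': 40
signal: 0.8
radius: 10.0
cutoff: 14.0
egat_layers: 5
egnn_layers: 7
focal_alpha: 0.25
focal_gamma: 2.0
threshold: 0.5
seed: 42
fusion: muse
egnn_coord_sum: no
folds: 5
epochs: 100
out: ppisite_out
help: no
version: 0.1.0
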