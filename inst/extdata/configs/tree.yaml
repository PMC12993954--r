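# SWC-tree generator defaults: a moderately ramified arbor with filopodia.
type: tree
n_primary: 4
branch_probability: 0.3
segment_length_range: [6, 15]
max_depth: 4
n_filopodia: 5
filopodia_length_range: [1, 4.5]
seed: 1
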