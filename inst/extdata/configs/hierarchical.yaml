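# Nested animal/slice/cell measurement table.
type: hierarchical
n_animals_per_group: 4
n_slices_per_animal: 3
n_cells_per_slice: 5
beta0: 0
beta1: 1
sd_animal: 0.5
sd_slice: 0.25
sd_cell: 1
seed: 1
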