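# Surveillance-movie generator, treated condition: motility reduced to 40%
# (the direction of an actin-branching blockade).
type: motility
image_shape: [128, 128]
n_frames: 8
frame_interval: 30
pixel_size: 0.25
n_primary_processes: 6
tip_extension_rate: 0.8
tip_retraction_rate: 0.8
motility_scale: 0.4
process_thickness: 3
initial_length_range: [5, 10]
seed: 1
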