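# Lesion-front convergence movie: 15 um lesion, 2 um/min front speed.
type: chemotaxis
image_shape: [360, 360]
n_frames: 11
frame_interval: 30
pixel_size: 0.25
lesion_diameter: 15
n_processes: 48
convergence_speed: 2
initial_front_radius: 40
seed: 1
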