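# Default pipeline configuration (all values equal the built-in defaults)
bone_threshold: auto
connectivity: 26
stack_window: 3
refine_fraction: 0.3
k_clusters: 3
max_iter: 100
restarts: 3
min_region_px: 3
min_regions: 3
min_airway_px: 4
smoothing_window: 5
seed: 1
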