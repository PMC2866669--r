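# Pipeline parameters (defaults shown; one key = value per line).
# Flags on the command line override these; these override the defaults.
k_sigma = 3.0
t_min = 10
median_radius = 1
h = 7
dome_threshold = 0
seed_min_voxels = 20
min_volume_um3 = 3.172
# intersection_pct = 50       # adjacent-slice merge, disabled by default
seed_connectivity = 18
label_connectivity = 6
voxel_size = 0.2,0.2,0.5
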