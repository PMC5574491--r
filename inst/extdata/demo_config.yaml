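# Desk-scale demo screen configuration (see ?screen_config for all keys).
plate_shape: [4, 8]
n_planes: 5
z_interval_um: 50
pixel_size_um: 3.25
image_size: [192, 192]
noise_sd: 300
swelling_factor: 1.6
cysts_per_well: [6, 10]
radius_mean_px: 14
radius_sd_px: 2.5
controls:
  unstimulated: 4
  stimulated: 4
  reference_inhibitor: 0
doses_um: [0.1, 1.0]
replicates: 4
seed: 1
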