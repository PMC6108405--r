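# Generic fragmented forest stand with canopy gaps.
type: forest
canopy_base_height: 8
canopy_top_height: 20
canopy_gap_prob: 0.25
understory_density: 0.05
trunk_count: 15
trunk_radius: 0.25
stand_radius: 30
second_return_prob: 0.25
reflectance_mean: 0.45
reflectance_sd: 0.1
range_noise_sd_m: 0.05
max_range_clip: 40
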