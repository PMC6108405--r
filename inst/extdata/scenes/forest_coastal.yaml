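# Coastal tropical rainforest: more open at the optical plane.
type: forest
canopy_base_height: 12
canopy_top_height: 26
canopy_gap_prob: 0.15
understory_density: 0.06
trunk_count: 15
trunk_radius: 0.3
stand_radius: 30
second_return_prob: 0.3
reflectance_mean: 0.38
reflectance_sd: 0.08
range_noise_sd_m: 0.05
max_range_clip: 40
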