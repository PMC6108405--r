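# Temperate stand: sparser understory, larger canopy gaps, brighter
# returns at 905 nm. Illustrative contrast, not calibrated to any site.
type: forest
canopy_base_height: 10
canopy_top_height: 22
canopy_gap_prob: 0.35
understory_density: 0.02
trunk_count: 12
trunk_radius: 0.3
stand_radius: 30
second_return_prob: 0.18
reflectance_mean: 0.55
reflectance_sd: 0.1
range_noise_sd_m: 0.05
max_range_clip: 40
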