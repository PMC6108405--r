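# Inland tropical rainforest: denser subcanopy and epiphyte-laden trunks
# (smaller optical plane area, more vertical structure).
type: forest
canopy_base_height: 10
canopy_top_height: 26
canopy_gap_prob: 0.1
understory_density: 0.14
trunk_count: 22
trunk_radius: 0.35
stand_radius: 30
second_return_prob: 0.32
reflectance_mean: 0.36
reflectance_sd: 0.08
range_noise_sd_m: 0.05
max_range_clip: 40
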