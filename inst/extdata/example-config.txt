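# ciliomorph detection configuration (all lengths in micrometres)
pixel_size_um = 0.5
canny_lower_factor = 0.67
canny_upper_factor = 1.33
min_length_um = 1
max_length_um = 15
min_aspect = 1.5
drop_border = false
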