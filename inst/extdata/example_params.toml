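# Standard analysis settings (these equal the package defaults).
tophat_radius_um = 20.0
threshold_corrected_units = 2.0
min_object_area_um2 = 50.0
edge_split = true
channel_of_interest = "green"
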