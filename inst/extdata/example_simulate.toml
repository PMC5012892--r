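# Minimal single-well simulation: 15 cells imaged every 10 min for 1 h.
seed = 11
n_cells = 15
field_px = [96, 96]
pixel_size_um = 2.0
particle_conc = 200.0      # ug/ml
duration_min = 60.0
frame_interval_min = 10.0
well_id = "B02"
n_images = 2
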