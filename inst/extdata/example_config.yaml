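# Processing configuration for the dual-plate posturography pipeline.
# Any key omitted here keeps its protocol default.
cutoff_hz: 10          # low-pass cutoff (Hz), zero-phase Butterworth
filter_order: 4        # design order, applied forward and backward
common_rate_hz: 20     # rate used for alignment and ellipse area
bipedal_segment_s: 20  # analysis window, two-leg tasks (s)
unipedal_segment_s: 15 # analysis window, one-leg tasks (s)
board_sensor_span_ml: 43.3   # cm between left/right sensor pairs
board_sensor_span_ap: 23.8   # cm between top/bottom sensor pairs
plate_top_offset_cm: 5.3     # plate origin -> board surface (moment arm)
board_mass_kg: 3.9           # weight correction for the stacked board
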