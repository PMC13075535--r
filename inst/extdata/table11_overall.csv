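factor,optimal_setting
torso_angle_deg,0.0
lever_distance_mm,37.5
lever_orientation_deg,15.0
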