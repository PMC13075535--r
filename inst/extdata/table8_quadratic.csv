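muscle,factor,b0,b1,b2,residual_standard_error,r_squared_pct
BBL,lever_distance_mm,42.14,-0.0710,0.000753,4.96,4.8
BBL,torso_angle_deg,38.46,0.0658,0.001659,3.98,38.7
BBL,lever_orientation_deg,41.14,-0.04083,0.000976,4.91,6.8
TBL,lever_distance_mm,60.13,-0.4210,0.004890,11.79,30.6
TBL,torso_angle_deg,47.96,0.6270,-0.00429,9.81,52.0
TBL,lever_orientation_deg,53.11,0.0051,0.01057,13.05,15.1
BRD,lever_distance_mm,89.46,0.0796,0.000036,25.41,2.6
BRD,torso_angle_deg,72.16,0.470,0.00992,15.35,64.5
BRD,lever_orientation_deg,106.7,-0.0318,-0.02177,23.11,19.4
PDT,lever_distance_mm,72.00,-0.4517,0.004103,19.27,9.6
PDT,torso_angle_deg,50.51,0.863,-0.00571,14.43,49.3
PDT,lever_orientation_deg,59.58,-0.2776,-0.01155,17.48,25.6
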