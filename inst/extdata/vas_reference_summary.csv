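attribute,mean,sd
comfort,3.33,1.58
stability,5.44,1.74
driving_control,6.00,1.22
perception,3.89,1.17
maneuverability,5.11,1.17
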