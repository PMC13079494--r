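day_id,flow_L_day,population
1,228700000,820000000
2,229000000,820000000
3,228900000,820000000
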