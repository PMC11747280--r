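bait_id	chrom	pos
Bait1	chr17	18057102
Bait2	chr15	59225292
Bait3	chr4	178363578
Bait4	chr7	29604609
Bait5	chr16	56966412
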