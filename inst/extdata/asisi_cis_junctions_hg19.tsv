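junction_id	chrom	pos_a	pos_b	distance_kbp
J1	chr22	20785436	20850310	68
J2	chr9	130693173	130889410	196
J3	chr6	27145369	27661903	516
J4	chr3	98618167	99536967	918
J5	chr7	92157735	92861493	703
J6	chr11	118965052	120196325	1231
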