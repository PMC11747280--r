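# breakscape demo configuration: small synthetic experiment
[simulate]
seed = 7
n_chrom = 2
chrom_length = 10000000
tad_mean_size = 1000000
n_asisi = 4
n_cut = 2
dsb_min_spacing = 2000000
hic_resolution = 20000
hic_depth = 300000
junction_n_junctions = 1500

[run]
genotype = RAD21-
min_fc = 3
flank = 500
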