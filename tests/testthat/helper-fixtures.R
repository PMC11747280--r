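# Shared fixtures for the test suite.

# The worked 3-bin matrix used throughout the Hi-C tests.
worked_matrix <- function() {
  m <- matrix(c(4, 3, 1,
                3, 4, 1,
                1, 1, 4), 3, 3, byrow = TRUE)
  lay <- genome_layout("chrW", 300)
  contact_matrix("chrW", "chrW", 100, m, lay)
}

# A small, fast simulation configuration for structural tests.
small_config <- function(seed, ...) {
  sim_config(seed = seed, n_chrom = 1, chrom_length = 8e6,
             tad_mean_size = 1e6, n_asisi = 2, n_cut = 2,
             dsb_min_spacing = 2e6,
             hic = list(resolution = 2e4, depth = 3e5), ...)
}

# Null configuration: every injected effect at 1.
null_config <- function(seed) {
  sim_config(seed = seed, n_chrom = 1, chrom_length = 1e7,
             n_asisi = 3, n_cut = 2,
             chip = list(depth = 10,
                         anchor_fc = c(WT = 1, `RAD21-` = 1, SMC1A_Pdef = 1,
                                       ATMi = 1, `LIG4-` = 1)),
             hic = list(resolution = 2e4, depth = 2e6,
                        intra_damage_boost = 1,
                        gamma = c(WT = 1, `RAD21-` = 1, SMC1A_Pdef = 1,
                                  ATMi = 1, `LIG4-` = 1)))
}

packaged_file <- function(name) {
  system.file("extdata", name, package = "breakscape", mustWork = TRUE)
}
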