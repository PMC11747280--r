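#' Genotype and damage condition labels
#'
#' The closed sets of condition labels understood by the simulator and the
#' pipeline: genotypes `WT`, `RAD21-` (cohesin degron), `SMC1A_Pdef`
#' (phosphorylation-deficient SMC1A), `ATMi` (ATM kinase inhibition),
#' `LIG4-` (ligase-4 knockout, NHEJ-blocked); damage `NT` (untreated) and
#' `DSB` (AsiSI breaks induced).
#'
#' @export
GENOTYPES <- c("WT", "RAD21-", "SMC1A_Pdef", "ATMi", "LIG4-")

#' @rdname GENOTYPES
#' @export
DAMAGE_STATES <- c("NT", "DSB")

check_condition <- function(genotype, damage) {
  if (!genotype %in% GENOTYPES)
    stop("unknown genotype '", genotype, "'; must be one of ",
         paste(GENOTYPES, collapse = ", "))
  if (!damage %in% DAMAGE_STATES)
    stop("unknown damage state '", damage, "'")
  invisible(TRUE)
}

#' Simulation configuration
#'
#' Parameters of the synthetic genome and data generator. Defaults encode the
#' study conditions the package is designed around: a TAD-partitioned genome
#' with CTCF/cohesin anchors, AsiSI cut sites placed near anchors and >= 2 Mb
#' apart, megabase-scale damage (gamma-H2AX) domains, damage-induced anchor
#' enrichment mirroring the measured fold changes (1.43 for WT, 1.17 for
#' SMC1A_Pdef, 1.73 for LIG4-), distance-decay contact matrices with TAD
#' blocks, a small damage-specific intra-domain gain (1.02) and DSB-DSB
#' domain clustering under cohesin loss (1.16), and junction libraries whose
#' translocation rates mirror the measured condition fold changes (4.3-fold
#' under cohesin depletion).
#'
#' @param seed mandatory integer seed; every simulated object is a pure
#'   function of (config, seed).
#' @param n_chrom,chrom_length number and size (bp) of chromosomes.
#' @param tad_mean_size mean TAD size in bp.
#' @param anchors_per_tad interior anchors per TAD (TAD borders always carry
#'   an anchor).
#' @param n_asisi number of AsiSI recognition sites placed.
#' @param n_cut number of sites actually broken (`<= n_asisi`).
#' @param dsb_min_spacing minimum pairwise spacing of AsiSI sites in bp.
#' @param with_sequence generate genome sequence with motifs planted at the
#'   AsiSI sites (slow for large genomes; default off).
#' @param chip,hic,junction named lists overriding individual parameters of
#'   the ChIP, Hi-C and junction-library models; see Details.
#'
#' @details
#' ChIP parameters: `bin_size` (100 bp, the rpkm window), `baseline_height`
#' (anchor peak height, rpkm), `anchor_fc` (named per-genotype damage
#' enrichment factor applied to anchors inside damaged domains),
#' `rad21_depletion` (residual RAD21 peak scale in `RAD21-` cells),
#' `mre11_height`, `gh2ax_height`, `gh2ax_halfwidth` (damage-domain
#' half-width, bp), `background` (mean background rpkm), `bg_log_sd` and
#' `bg_segment` (log-sd and segment size of the shared regional background
#' field), `depth` (Poisson counts simulated per rpkm unit per bin),
#' `peak_halfwidth` (triangular peak half-width), `n_ctcf_only`,
#' `n_rad21_only` (non-anchor peak counts).
#'
#' Hi-C parameters: `resolution` (intra, bp), `alpha` (distance-decay
#' exponent), `tad_boost` (intra-TAD contact multiplier; forced to 1 in the
#' damaged `RAD21-` condition), `intra_damage_boost` (same-damaged-domain
#' multiplier under damage), `gamma` (named per-genotype multiplier for bin
#' pairs in two distinct damaged domains under damage), `trans_resolution`
#' (250 kb), `trans_baseline` (mean trans counts per bin pair),
#' `trans_gamma` (per-genotype damaged-pair trans multiplier),
#' `trans_log_sd` (per-bin coverage-bias log-sd), `depth` (expected intra
#' counts per chromosome).
#'
#' Junction parameters: `n_junctions`, `mh_geometric_p` (geometric parameter
#' of the microhomology-length distribution), `bait_proximal_fraction`,
#' `translocation_rate` (named per-genotype fraction of junctions landing at
#' other cut sites; remainder is dispersed background), `prey_scatter_sd`
#' (bp scatter of prey positions around cut sites), `flank_length` (20 nt),
#' `mh_max` (cap on simulated microhomology length).
#'
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_chrom = 2,
                       chrom_length = 2e7,
                       tad_mean_size = 1e6,
                       anchors_per_tad = 1,
                       n_asisi = 8,
                       n_cut = 4,
                       dsb_min_spacing = 2e6,
                       with_sequence = FALSE,
                       chip = list(),
                       hic = list(),
                       junction = list()) {
  if (missing(seed) || is.null(seed) || is.na(seed))
    stop("sim_config: seed is mandatory")
  chip_defaults <- list(
    bin_size = 100,
    baseline_height = 50,
    anchor_fc = c(WT = 1.43, `RAD21-` = 1.0, SMC1A_Pdef = 1.17,
                  ATMi = 1.14, `LIG4-` = 1.73),
    rad21_depletion = 0.05,
    mre11_height = 30,
    gh2ax_height = 10,
    gh2ax_halfwidth = 1e6,
    background = 1.0,
    bg_log_sd = 0.5,
    bg_segment = 1e5,
    depth = 2,
    peak_halfwidth = 500,
    n_ctcf_only = 30,
    n_rad21_only = 10)
  hic_defaults <- list(
    resolution = 1e4,
    alpha = 1.0,
    tad_boost = 2.0,
    intra_damage_boost = 1.02,
    gamma = c(WT = 1.0, `RAD21-` = 1.16, SMC1A_Pdef = 1.04,
              ATMi = 1.03, `LIG4-` = 1.0),
    trans_resolution = 2.5e5,
    trans_baseline = 2.0,
    trans_gamma = c(WT = 1.31, `RAD21-` = 1.39, SMC1A_Pdef = 1.31,
                    ATMi = 1.10, `LIG4-` = 1.0),
    trans_log_sd = 0.5,
    depth = 1e6)
  junction_defaults <- list(
    n_junctions = 5000,
    mh_geometric_p = 2 / 3,
    bait_proximal_fraction = 0.2,
    translocation_rate = c(WT = 0.15, `RAD21-` = 0.645, SMC1A_Pdef = 0.315,
                           ATMi = 0.285, `LIG4-` = 0.015),
    prey_scatter_sd = 800,
    flank_length = 20,
    mh_max = 15)
  cfg <- list(seed = as.integer(seed), n_chrom = n_chrom,
              chrom_length = chrom_length, tad_mean_size = tad_mean_size,
              anchors_per_tad = anchors_per_tad, n_asisi = n_asisi,
              n_cut = n_cut, dsb_min_spacing = dsb_min_spacing,
              with_sequence = isTRUE(with_sequence),
              chip = utils::modifyList(chip_defaults, chip),
              hic = utils::modifyList(hic_defaults, hic),
              junction = utils::modifyList(junction_defaults, junction))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_cut > cfg$n_asisi)
    stop("sim_config: n_cut (", cfg$n_cut, ") exceeds n_asisi (",
         cfg$n_asisi, ")")
  fc <- c(cfg$chip$anchor_fc, cfg$hic$tad_boost, cfg$hic$intra_damage_boost,
          cfg$hic$gamma, cfg$hic$trans_gamma)
  if (any(fc <= 0)) stop("sim_config: fold-change parameters must be > 0")
  if (cfg$junction$mh_geometric_p <= 0 || cfg$junction$mh_geometric_p > 1)
    stop("sim_config: mh_geometric_p must be in (0, 1]")
  tr <- cfg$junction$translocation_rate
  if (any(tr + cfg$junction$bait_proximal_fraction > 1))
    stop("sim_config: translocation_rate + bait_proximal_fraction must be <= 1")
  invisible(cfg)
}

# Derived substream seed; keeps seeds well below 2^31 for small base seeds.
stream_seed <- function(cfg, module, genotype = "WT", damage = "NT",
                        extra = 0L) {
  cfg$seed + module * 100000L + match(genotype, GENOTYPES) * 1000L +
    match(damage, DAMAGE_STATES) * 100L + as.integer(extra)
}
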