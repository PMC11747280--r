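jrec <- function(prey_chrom, prey_pos, prey_strand = "+",
                 bait_chrom = "chr7", bait_pos = 29604608,
                 bait_flank = "ACGTACGTACGTACGTACGT",
                 prey_flank = "TTTTTTTTTTTTTTTTTTTT") {
  n <- length(prey_pos)
  data.frame(read_id = sprintf("r%03d", seq_len(n)),
             bait_chrom = bait_chrom, bait_pos = bait_pos,
             bait_strand = "+",
             prey_chrom = rep_len(prey_chrom, n), prey_pos = prey_pos,
             prey_strand = rep_len(prey_strand, n),
             bait_flank = bait_flank, prey_flank = prey_flank,
             stringsAsFactors = FALSE)
}

test_that("bait-proximal filtering partitions exactly at the 20 kb window", {
  bait <- list(chrom = "chr7", pos = 29604608)  # assayed bait 4 (0-based)
  recs <- jrec("chr7", c(29609999, 29699999))
  parts <- filter_bait_proximal(recs, bait)
  # 5,391 bp away: removed; 95,391 bp away: kept
  expect_equal(parts$removed$prey_pos, 29609999)
  expect_equal(parts$kept$prey_pos, 29699999)

  # the rule only applies on the bait chromosome
  far <- jrec("chr22", 29604608)
  expect_equal(nrow(filter_bait_proximal(far, bait)$removed), 0)

  # exact partition on a simulated library
  cfg <- small_config(41, junction = list(n_junctions = 500))
  sim <- build_layout(cfg)
  jx <- simulate_junctions(sim, sim$truth$cut_ids[1])
  bt <- list(chrom = jx$bait_chrom[1], pos = jx$bait_pos[1])
  p <- filter_bait_proximal(jx, bt)
  expect_equal(nrow(p$kept) + nrow(p$removed), nrow(jx))
  expect_equal(intersect(p$kept$read_id, p$removed$read_id), character(0))
  expect_true(all(abs(p$removed$prey_pos - bt$pos) <= 2e4))
})

test_that("cis/trans classification is by chromosome identity and partitions", {
  bait <- list(chrom = "chr7", pos = 29604608)
  recs <- jrec(c("chr7", "chr2"), c(30104608, 29604608))
  cls <- classify_cis_trans(recs, bait)
  expect_equal(cls, c("cis_deletion", "translocation"))
  expect_equal(length(cls), nrow(recs))
})

test_that("damage context assignment respects the fixed precedence", {
  dsbs <- dsb_sites("d1", "chr1", 5e6, 5e6 + 8)
  doms <- damage_domains("chr1", 4e6, 6e6, damaged = TRUE)
  ctx <- function(ch, pos) assign_damage_context(jrec(ch, pos), dsbs, doms)
  expect_equal(ctx("chr1", 5e6 + 1000), "break_site")  # in-domain too
  expect_equal(ctx("chr1", 5.5e6), "gh2ax_domain")
  expect_equal(ctx("chr1", 5e6 + 2500 + 4), "break_site")  # window inclusive
  expect_equal(ctx("chr1", 9e6), "outside")
  expect_equal(ctx("chr5", 5e6), "outside")
})

test_that("microhomology length matches a brute-force oracle", {
  expect_equal(microhomology_length("GGGGTACG", "ACGTCCCC"), 3)
  expect_equal(microhomology_length("AAAA", "CCCC"), 0)
  expect_equal(microhomology_length("ACGT", "ACGT"), 4)
  expect_equal(microhomology_length("TTAN", "ANCC"), 0)  # N never matches
  expect_error(microhomology_length("", "ACGT"), "empty")

  set.seed(77)
  alphabet <- c("A", "C", "G", "T", "N")
  for (rep in 1:100) {
    lb <- sample(4:20, 1); lp <- sample(4:20, 1)
    b <- paste(sample(alphabet, lb, TRUE, prob = c(.24, .24, .24, .24, .04)),
               collapse = "")
    p <- paste(sample(alphabet, lp, TRUE, prob = c(.24, .24, .24, .24, .04)),
               collapse = "")
    # bias toward real overlaps half the time
    if (rep %% 2 == 0) {
      k <- sample(1:min(lb, lp), 1)
      substr(p, 1, k) <- substr(b, lb - k + 1, lb)
    }
    expect_equal(microhomology_length(b, p), oracle_mh(b, p))
  }
})

test_that("junction distances reproduce the assayed break-pair table", {
  tab <- read.delim(packaged_file("asisi_cis_junctions_hg19.tsv"))
  # row 1 of the table is excluded: its printed distance is inconsistent
  # with its own coordinates (68 vs a computed 64 kbp)
  tab <- tab[tab$junction_id != "J1", ]
  got <- junction_distance_kbp(tab$pos_a, tab$pos_b, tab$chrom, tab$chrom)
  expect_equal(got, tab$distance_kbp)
  expect_equal(junction_distance_kbp(5, 5), 0L)
  expect_error(junction_distance_kbp(1, 2, "chr1", "chr2"), "different")
})

test_that("binned junction counts deduplicate by coordinate and strand", {
  recs <- jrec("chr1", c(1050, 1900, 1900, 2500), c("+", "+", "+", "-"))
  b <- bin_junction_counts(recs)
  expect_equal(b$count[b$bin_start == 1000], 2)  # 1900 duplicate collapsed
  expect_equal(b$count[b$bin_start == 2000], 1)
  expect_equal(sum(b$count), 3)
  # same coordinate on opposite strands is two events
  recs2 <- jrec("chr1", c(1900, 1900), c("+", "-"))
  expect_equal(bin_junction_counts(recs2)$count, 2)
  expect_equal(nrow(bin_junction_counts(recs[0, ])), 0)
})

test_that("condition fold change normalizes to library size", {
  a <- data.frame(site = "s1", count = 430)
  b <- data.frame(site = "s1", count = 100)
  r <- condition_fold_change(a, b, 5000, 5000)
  expect_equal(r$aggregate_fc, 4.3, tolerance = 1e-2)
  expect_equal(r$per_site$fc, 4.3, tolerance = 1e-2)

  r1 <- condition_fold_change(a, a, 5000, 5000)
  expect_equal(r1$aggregate_fc, 1.0)

  # library-size normalization: doubling a library's total halves its rates
  r2 <- condition_fold_change(a, a, 5000, 10000)
  expect_gt(r2$aggregate_fc, 1.9)
  expect_error(condition_fold_change(a, b, 0, 1), "total")
})

test_that("injected prey-sampling rate ratio is recovered from libraries", {
  cfg_lo <- sim_config(seed = 31, n_chrom = 3, n_asisi = 12, n_cut = 9,
                       junction = list(n_junctions = 5000,
                                       translocation_rate = c(
                                         WT = 0.2, `RAD21-` = 0.2,
                                         SMC1A_Pdef = 0.2, ATMi = 0.2,
                                         `LIG4-` = 0.2)))
  cfg_hi <- sim_config(seed = 31, n_chrom = 3, n_asisi = 12, n_cut = 9,
                       junction = list(n_junctions = 5000,
                                       translocation_rate = c(
                                         WT = 0.4, `RAD21-` = 0.4,
                                         SMC1A_Pdef = 0.4, ATMi = 0.4,
                                         `LIG4-` = 0.4)))
  sim <- build_layout(cfg_lo)
  bait_id <- sim$truth$cut_ids[1]
  j_lo <- simulate_junctions(sim, bait_id, config = cfg_lo)
  j_hi <- simulate_junctions(sim, bait_id, config = cfg_hi)
  site_counts <- function(jx) {
    bt <- list(chrom = jx$bait_chrom[1], pos = jx$bait_pos[1])
    kept <- filter_bait_proximal(jx, bt)$kept
    key <- paste(kept$prey_chrom, kept$prey_pos, kept$prey_strand)
    kept <- kept[!duplicated(key), ]
    cuts <- sim$truth$cuts[sim$truth$cuts$id != bait_id, ]
    data.frame(site = cuts$id, count = vapply(seq_len(nrow(cuts)), function(i) {
      sum(kept$prey_chrom == cuts$chrom[i] &
            abs(kept$prey_pos - cut_midpoint(cuts[i, ])) <= 2500)
    }, numeric(1)))
  }
  r <- condition_fold_change(site_counts(j_hi), site_counts(j_lo),
                             nrow(j_hi), nrow(j_lo))
  expect_gt(r$aggregate_fc, 1.8)
  expect_lt(r$aggregate_fc, 2.2)
})

test_that("microhomology profiles summarize the geometric draw", {
  p0 <- mh_profile(rep(0L, 10))
  expect_equal(p0$fraction_mh, 0)
  expect_equal(p0$mean_mh, 0)

  set.seed(55)
  draws <- rgeom(10000, 0.5)
  p <- mh_profile(draws)
  expect_gt(p$mean_mh, 0.9)   # geometric mean (1-p)/p = 1
  expect_lt(p$mean_mh, 1.1)
  expect_equal(sum(p$histogram$count), 10000)
  expect_equal(p$histogram$mh_len, 0:max(draws))
})

test_that("annotation chain partitions every record exactly once", {
  cfg <- small_config(61, junction = list(n_junctions = 800))
  sim <- build_layout(cfg)
  jx <- simulate_junctions(sim, sim$truth$cut_ids[1])
  bt <- sim$truth$cuts[sim$truth$cuts$id == sim$truth$cut_ids[1], ]
  bt$pos <- cut_midpoint(bt)
  ann <- annotate_junctions(jx, bt, sim$truth$cuts,
                            sim$truth$damaged_domains)
  expect_equal(nrow(ann$records) + nrow(ann$removed), nrow(jx))
  expect_equal(sum(ann$class_counts), nrow(ann$records))
  expect_true(all(ann$records$context %in%
                    c("break_site", "gh2ax_domain", "outside")))
  expect_equal(sum(table(ann$records$context)), nrow(ann$records))
})
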