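test_that("build_layout is deterministic and satisfies its invariants", {
  cfg <- sim_config(seed = 7)
  s1 <- build_layout(cfg)
  s2 <- build_layout(cfg)
  expect_identical(s1$tads, s2$tads)
  expect_identical(s1$dsbs, s2$dsbs)
  expect_identical(s1$truth$bg_field, s2$truth$bg_field)

  # TADs tile each chromosome and never span chromosomes
  for (ch in s1$layout$chrom_names) {
    tt <- s1$tads[s1$tads$chrom == ch, ]
    tt <- tt[order(tt$start), ]
    expect_equal(tt$start[1], 0)
    expect_equal(tt$end[nrow(tt)], unname(s1$layout$chrom_lengths[ch]))
    expect_equal(tt$start[-1], tt$end[-nrow(tt)])
  }

  # AsiSI spacing respected per chromosome
  for (ch in unique(s1$dsbs$chrom)) {
    st <- sort(s1$dsbs$start[s1$dsbs$chrom == ch])
    if (length(st) > 1)
      expect_true(all(diff(st) >= cfg$dsb_min_spacing))
  }

  # cut sites are a subset of AsiSI sites
  expect_true(all(s1$truth$cut_ids %in% s1$dsbs$id))
  expect_equal(length(s1$truth$cut_ids), cfg$n_cut)

  # damaged truth domains are non-overlapping and centered on cuts
  dd <- s1$truth$damaged_domains
  expect_true(all(dd$damaged))
  mids <- cut_midpoint(s1$truth$cuts)
  inside <- mapply(function(ch, p) point_in <- any(
    dd$chrom == ch & dd$start <= p & p < dd$end),
    s1$truth$cuts$chrom, mids)
  expect_true(all(inside))
})

test_that("infeasible configurations are refused with guidance", {
  expect_error(sim_config(seed = 1, n_asisi = 2, n_cut = 3), "n_cut")
  cfg <- sim_config(seed = 1, n_chrom = 1, chrom_length = 6e6,
                    n_asisi = 10, n_cut = 2, dsb_min_spacing = 2e6)
  expect_error(build_layout(cfg), "infeasible")
  expect_error(sim_config(seed = NA), "seed")
})

test_that("planted sequence carries every AsiSI site", {
  cfg <- sim_config(seed = 5, n_chrom = 1, chrom_length = 4e6,
                    n_asisi = 2, n_cut = 1, dsb_min_spacing = 5e5,
                    with_sequence = TRUE)
  sim <- build_layout(cfg)
  found <- find_asisi_sites(sim$layout)
  expect_true(all(sim$dsbs$start %in% found$start))
  for (i in seq_len(nrow(sim$dsbs)))
    expect_equal(substr(sim$layout$sequence[[sim$dsbs$chrom[i]]],
                        sim$dsbs$start[i] + 1, sim$dsbs$start[i] + 8),
                 "GCGATCGC")
})

test_that("simulated ChIP tracks are deterministic with condition structure", {
  cfg <- small_config(11)
  sim <- build_layout(cfg)
  a <- simulate_chip(sim, "WT", "DSB")
  b <- simulate_chip(sim, "WT", "DSB")
  expect_identical(a$tracks$RAD21$values, b$tracks$RAD21$values)
  expect_identical(a$peaks, b$peaks)

  nt <- simulate_chip(sim, "WT", "NT")
  # no MRE11 peaks without damage: the mean near cut sites stays at background
  mids <- cut_midpoint(sim$truth$cuts)
  for (i in seq_along(mids)) {
    core <- interval_mean(nt$tracks$MRE11, sim$truth$cuts$chrom[i],
                          mids[i] - 500, mids[i] + 500)
    dsb <- interval_mean(a$tracks$MRE11, sim$truth$cuts$chrom[i],
                         mids[i] - 500, mids[i] + 500)
    expect_lt(core, 5)
    expect_gt(dsb, 10)
  }
  expect_error(simulate_chip(sim, "XX", "NT"), "genotype")
})

test_that("a unit anchor factor leaves inside and outside anchors equal", {
  cfg <- null_config(23)
  sim <- build_layout(cfg)
  nt <- simulate_chip(sim, "WT", "NT")
  ds <- simulate_chip(sim, "WT", "DSB")
  anchors <- call_anchor_sites(ds$peaks$RAD21, ds$peaks$CTCF)
  r <- anchor_domain_enrichment(anchors, sim$truth$damaged_domains,
                                ds$tracks$RAD21, nt$tracks$RAD21)
  expect_gt(r$n_inside, 1)
  expect_gt(r$n_outside, 1)
  expect_lt(abs(r$mean_fc_inside - r$mean_fc_outside), 0.05)
  two_sided <- welch_t(r$table$fold_change[r$table$category == "inside"],
                       r$table$fold_change[r$table$category == "outside"],
                       tails = "two")
  expect_gt(two_sided$p_value, 0.01)
})

test_that("simulated contacts are symmetric, deterministic, with TAD structure", {
  cfg <- small_config(19)
  sim <- build_layout(cfg)
  a <- simulate_contacts(sim, "WT", "NT")
  b <- simulate_contacts(sim, "WT", "NT")
  expect_identical(a$intra, b$intra)
  m <- a$intra[[1]]
  expect_equal(m$counts, t(m$counts))
  expect_true(all(m$counts >= 0))

  # without a TAD boost, O/E inside TADs is flat around 1
  cfg0 <- sim_config(seed = 19, n_chrom = 1, chrom_length = 8e6,
                     n_asisi = 2, n_cut = 2,
                     hic = list(resolution = 2e4, depth = 1e6,
                                tad_boost = 1, intra_damage_boost = 1,
                                gamma = c(WT = 1, `RAD21-` = 1,
                                          SMC1A_Pdef = 1, ATMi = 1,
                                          `LIG4-` = 1)))
  sim0 <- build_layout(cfg0)
  m0 <- oe_normalize(simulate_contacts(sim0, "WT", "DSB")$intra[[1]])
  scores <- sapply(which(!sim0$tads$damaged), function(i)
    tryCatch(intra_domain_score(m0, sim0$tads[i, ])$score,
             error = function(e) NA))
  expect_gt(mean(scores, na.rm = TRUE), 0.95)
  expect_lt(mean(scores, na.rm = TRUE), 1.05)

  # cohesin depletion under damage lowers intra-TAD O/E relative to WT
  wt <- oe_normalize(simulate_contacts(sim, "WT", "DSB")$intra[[1]])
  rd <- oe_normalize(simulate_contacts(sim, "RAD21-", "DSB")$intra[[1]])
  tad_score <- function(oe) mean(sapply(seq_len(nrow(sim$tads)), function(i)
    tryCatch(intra_domain_score(oe, sim$tads[i, ])$score,
             error = function(e) NA)), na.rm = TRUE)
  expect_gt(tad_score(wt), tad_score(rd))
})

test_that("junction libraries follow the configured structure deterministically", {
  cfg <- small_config(29, junction = list(n_junctions = 400))
  sim <- build_layout(cfg)
  bait <- sim$truth$cut_ids[1]
  a <- simulate_junctions(sim, bait)
  b <- simulate_junctions(sim, bait)
  expect_identical(a, b)
  expect_error(simulate_junctions(sim, "nope"), "not a cut site")

  # degenerate geometric distribution: p = 1 means no microhomology
  cfg1 <- small_config(29, junction = list(n_junctions = 200,
                                           mh_geometric_p = 1))
  sim1 <- build_layout(cfg1)
  j1 <- simulate_junctions(sim1, sim1$truth$cut_ids[1])
  expect_true(all(microhomology_length(j1$bait_flank, j1$prey_flank) == 0))

  # all-bait-proximal library is fully removed by the bait filter
  cfg2 <- small_config(29, junction = list(
    n_junctions = 200, bait_proximal_fraction = 1,
    translocation_rate = c(WT = 0, `RAD21-` = 0, SMC1A_Pdef = 0,
                           ATMi = 0, `LIG4-` = 0)))
  sim2 <- build_layout(cfg2)
  j2 <- simulate_junctions(sim2, sim2$truth$cut_ids[1])
  bt <- sim2$truth$cuts[sim2$truth$cuts$id == sim2$truth$cut_ids[1], ]
  bt$pos <- cut_midpoint(bt)
  parts <- filter_bait_proximal(j2, bt)
  expect_equal(nrow(parts$kept), 0)
  expect_equal(nrow(parts$removed), 200)

  # flanks embed exactly the drawn microhomology
  expect_equal(microhomology_length(a$bait_flank, a$prey_flank), a$sim_mh)
})

test_that("prey site usage tracks contact frequency", {
  cfg <- sim_config(seed = 11, n_chrom = 4, n_asisi = 24, n_cut = 21,
                    hic = list(resolution = 1e5),
                    junction = list(n_junctions = 5000))
  sim <- build_layout(cfg)
  hic <- simulate_contacts(sim, "RAD21-", "DSB")
  bait_id <- sim$truth$cut_ids[1]
  jx <- simulate_junctions(sim, bait_id, contacts = hic,
                           genotype = "RAD21-")
  cuts <- sim$truth$cuts
  bait <- cuts[cuts$id == bait_id, ]
  preys <- cuts[cuts$id != bait_id, ]
  score <- sapply(seq_len(nrow(preys)), function(i) {
    if (preys$chrom[i] == bait$chrom)
      return(trans_window_score(hic$intra[[bait$chrom]], cut_midpoint(bait),
                                cut_midpoint(preys[i, ]), warn = FALSE))
    key <- paste(bait$chrom, preys$chrom[i], sep = "|")
    if (!is.null(hic$inter[[key]]))
      trans_window_score(hic$inter[[key]], cut_midpoint(bait),
                         cut_midpoint(preys[i, ]), warn = FALSE)
    else
      trans_window_score(hic$inter[[paste(preys$chrom[i], bait$chrom,
                                          sep = "|")]],
                         cut_midpoint(preys[i, ]), cut_midpoint(bait),
                         warn = FALSE)
  })
  counts <- sapply(preys$id, function(id) sum(jx$sim_prey_id == id,
                                              na.rm = TRUE))
  expect_equal(length(counts), 20)
  expect_gt(cor(score, counts, method = "spearman"), 0.5)
})
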