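# One simulated WT experiment shared by the recovery tests in this file.
wt_cfg <- sim_config(seed = 7)
wt_sim <- build_layout(wt_cfg)
wt_nt <- simulate_chip(wt_sim, "WT", "NT")
wt_dsb <- simulate_chip(wt_sim, "WT", "DSB")

test_that("distance classification uses inclusive disjoint shells", {
  dsbs <- dsb_sites("d1", "chr1", 5e6, 5e6 + 1)
  pk <- function(ch, s) signal_peaks(ch, s - 500, s + 500, s, 1)
  expect_equal(classify_peak_distance(pk("chr1", 5e6 + 5000), dsbs), "D10K")
  expect_equal(classify_peak_distance(pk("chr1", 5e6 + 10000), dsbs), "D10K")
  expect_equal(classify_peak_distance(pk("chr1", 5e6 + 10001), dsbs), "D250K")
  expect_equal(classify_peak_distance(pk("chr1", 5e6 + 250000), dsbs), "D250K")
  expect_equal(classify_peak_distance(pk("chr1", 5e6 + 999999), dsbs), "D1M")
  expect_equal(classify_peak_distance(pk("chr1", 7e6 + 1), dsbs), "CTRL")
  # DSB-free chromosome is control chromatin
  expect_equal(classify_peak_distance(pk("chr9", 5e6), dsbs), "CTRL")
  expect_error(classify_peak_distance(pk("chr1", 1), dsbs[0, ]), "empty")

  # the categories partition any peak set
  set.seed(2)
  peaks <- signal_peaks(sample(c("chr1", "chr2"), 200, TRUE),
                        s <- sample(1e7, 200), s + 1000, s + 500, 1)
  cats <- classify_peak_distance(peaks, dsbs)
  expect_equal(sum(table(cats)), 200)
  expect_true(all(cats %in% c("D10K", "D250K", "D1M", "CTRL")))
})

test_that("fold changes use mean per-bp signal and the 0.1 pseudocount", {
  lay <- genome_layout("chr1", 4e6)
  tr <- function(x) coverage_track(100, list(chr1 = rep(x, 4e4)), lay)
  peaks <- signal_peaks("chr1", 1e5, 1e5 + 1000, 1e5 + 500, 1)
  dsbs <- dsb_sites("d", "chr1", 1e5, 1e5 + 8)
  r <- category_fold_change(peaks, dsbs, tr(1.9), tr(0.9))
  expect_equal(r$table$fold_change, 2.0)
  r2 <- category_fold_change(peaks, dsbs, tr(0.7), tr(0.7))
  expect_equal(r2$table$fold_change, 1.0)
  # empty categories report n = 0 without a test
  expect_equal(r$summary$n[r$summary$category == "CTRL"], 0)
  expect_true(is.na(r$summary$p_vs_ctrl[r$summary$category == "D10K"]))

  # pseudocount limit: doubling both tracks moves FC by well under 1%
  ra <- category_fold_change(peaks, dsbs, tr(40), tr(20))
  rb <- category_fold_change(peaks, dsbs, tr(80), tr(40))
  expect_lt(abs(ra$table$fold_change - rb$table$fold_change) /
              ra$table$fold_change, 0.01)
})

test_that("cumulative mode nests the distance categories", {
  dsbs <- dsb_sites("d1", "chr1", 5e6, 5e6 + 1)
  s <- 5e6 + c(5000, 100000, 800000, 3e6, 3.5e6)
  peaks <- signal_peaks("chr1", s - 500, s + 500, s, 1)
  lay <- genome_layout("chr1", 1e7)
  tr <- coverage_track(100, list(chr1 = rep(1, 1e5)), lay)
  disj <- category_fold_change(peaks, dsbs, tr, tr)$summary
  cum <- category_fold_change(peaks, dsbs, tr, tr, cumulative = TRUE)$summary
  expect_equal(disj$n, c(1, 1, 1, 2))
  expect_equal(cum$n, c(1, 2, 3, 2))
})

test_that("DSB calling recovers injected cuts with high precision and recall", {
  called <- call_dsb_sites(wt_dsb$tracks$MRE11, wt_sim$dsbs)
  truth <- wt_sim$truth$cut_ids
  recall <- mean(truth %in% called$id)
  precision <- if (nrow(called)) mean(called$id %in% truth) else 0
  expect_gte(recall, 0.95)
  expect_gte(precision, 0.95)

  # no calls from an undamaged track at min_fc = 3
  none <- call_dsb_sites(wt_nt$tracks$MRE11, wt_sim$dsbs)
  expect_equal(nrow(none), 0)

  # min_fc = 0 is the identity on candidates
  all_back <- call_dsb_sites(wt_dsb$tracks$MRE11, wt_sim$dsbs, min_fc = 0)
  expect_setequal(all_back$id, wt_sim$dsbs$id)

  expect_error(call_dsb_sites(wt_dsb$tracks$MRE11, wt_sim$dsbs, flank = 10),
               "flank")
})

test_that("anchor colocalization matches an all-pairs brute force", {
  r <- signal_peaks("chr1", 0, 1000, 100, 1)
  c1 <- signal_peaks("chr1", 0, 1000, 400, 1)
  expect_equal(nrow(call_anchor_sites(r, c1, 500)), 1)
  c2 <- signal_peaks("chr1", 200, 1400, 700, 1)
  expect_equal(nrow(call_anchor_sites(r, c2, 500)), 0)

  set.seed(14)
  n <- 1000
  s1 <- sort(sample(1e7, n)); s2 <- sort(sample(1e7, n))
  rad <- signal_peaks(sample(c("chr1", "chr2"), n, TRUE), s1, s1 + 1000,
                      s1 + 200, runif(n))
  ctf <- signal_peaks(sample(c("chr1", "chr2"), n, TRUE), s2, s2 + 1000,
                      s2 + 300, runif(n))
  got <- call_anchor_sites(rad, ctf, 500)
  want <- oracle_anchor_calls(rad, ctf, 500)
  expect_equal(got$summit, want$summit)
  expect_equal(got$chrom, want$chrom)
})

test_that("damage domain calling recovers the injected domains", {
  called <- call_dsb_sites(wt_dsb$tracks$MRE11, wt_sim$dsbs)
  dom <- call_damage_domains(wt_dsb$tracks$GH2AX, wt_nt$tracks$GH2AX,
                             dsbs = called)
  truth <- wt_sim$truth$damaged_domains
  expect_equal(nrow(dom), nrow(truth))
  expect_true(all(dom$damaged))
  for (i in seq_len(nrow(truth))) {
    hit <- dom[dom$chrom == truth$chrom[i] & dom$end > truth$start[i] &
                 dom$start < truth$end[i], ]
    expect_equal(nrow(hit), 1)
    inter <- min(hit$end, truth$end[i]) - max(hit$start, truth$start[i])
    uni <- max(hit$end, truth$end[i]) - min(hit$start, truth$start[i])
    expect_gte(inter / uni, 0.8)
  }

  # identical tracks yield no domains; a constant track is degenerate
  empty <- call_damage_domains(wt_nt$tracks$GH2AX, wt_nt$tracks$GH2AX)
  expect_equal(nrow(empty), 0)
  lay <- genome_layout("chr1", 1e6)
  flat <- coverage_track(100, list(chr1 = rep(1, 1e4)), lay)
  expect_error(call_damage_domains(flat, flat), "sd")
})

test_that("domains closer than the merge gap fuse; distant ones stay apart", {
  lay <- genome_layout("chr1", 6e6)
  set.seed(8)
  base <- rpois(600, 10)  # 10 kb bins
  plateau <- function(gap) {
    t <- base
    t[201:290] <- t[201:290] + 30                     # 2.0-2.9 Mb
    s2 <- 290 + gap / 1e4
    t[(s2 + 1):(s2 + 90)] <- t[(s2 + 1):(s2 + 90)] + 30
    coverage_track(1e4, list(chr1 = t), lay)
  }
  u <- coverage_track(1e4, list(chr1 = base + rpois(600, 1)), lay)
  near <- call_damage_domains(plateau(gap = 5e4), u, window = 1e4)
  expect_equal(nrow(near), 1)
  far <- call_damage_domains(plateau(gap = 2e5), u, window = 1e4)
  expect_equal(nrow(far), 2)
})

test_that("overlapping damage footprints form one merged truth domain", {
  # two cuts 150 kb apart: their +/- 1 Mb domains overlap and merge
  m <- merge_intervals(data.frame(chrom = "chr1",
                                  start = c(2e6, 2.15e6) - 1e6,
                                  end = c(2e6, 2.15e6) + 1e6))
  expect_equal(nrow(m), 1)
  expect_equal(m$start, 1e6)
  expect_equal(m$end, 3.15e6)
})

test_that("anchor enrichment inside damaged domains recovers injected factors", {
  # WT: injected 1.43 inside, 1 outside
  anchors <- call_anchor_sites(wt_dsb$peaks$RAD21, wt_dsb$peaks$CTCF)
  r <- anchor_domain_enrichment(anchors, wt_sim$truth$damaged_domains,
                                wt_dsb$tracks$RAD21, wt_nt$tracks$RAD21)
  expect_gt(r$mean_fc_inside, 1.33)
  expect_lt(r$mean_fc_inside, 1.53)
  expect_gt(r$mean_fc_outside, 0.95)
  expect_lt(r$mean_fc_outside, 1.05)
  expect_lt(r$test$p_value, 0.05)

  # all anchors outside: no inside mean, no test
  far <- damage_domains("chr1", 0, 1, damaged = TRUE)
  r0 <- anchor_domain_enrichment(anchors, far, wt_dsb$tracks$RAD21,
                                 wt_nt$tracks$RAD21)
  expect_equal(r0$n_inside, 0)
  expect_true(is.na(r0$mean_fc_inside))
  expect_null(r0$test)

  # LIG4- emulation: saturated repair, injected 1.73, seed-averaged
  means <- sapply(1:5, function(s) {
    cfg <- sim_config(seed = s)
    sim <- build_layout(cfg)
    nt <- simulate_chip(sim, "LIG4-", "NT")
    ds <- simulate_chip(sim, "LIG4-", "DSB")
    anc <- call_anchor_sites(ds$peaks$RAD21, ds$peaks$CTCF)
    anchor_domain_enrichment(anc, sim$truth$damaged_domains,
                             ds$tracks$RAD21, nt$tracks$RAD21)$mean_fc_inside
  })
  expect_gt(mean(means), 1.6)
  expect_lt(mean(means), 1.86)
})

test_that("distance-shell recovery: boosted shells versus control chromatin", {
  r <- category_fold_change(wt_dsb$peaks$RAD21, wt_sim$truth$cuts,
                            wt_dsb$tracks$RAD21, wt_nt$tracks$RAD21)
  sm <- r$summary
  d10k <- sm$mean_fc[sm$category == "D10K"]
  ctrl <- sm$mean_fc[sm$category == "CTRL"]
  expect_gt(d10k, 1.3)
  expect_lt(d10k, 1.5)
  expect_gt(ctrl, 0.95)
  expect_lt(ctrl, 1.05)
  # per-peak rows carry the invariant FC = (t + 0.1)/(u + 0.1)
  expect_equal(r$table$fold_change,
               (r$table$signal_treated + 0.1) /
                 (r$table$signal_untreated + 0.1))
})
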