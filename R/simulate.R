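#' Build a synthetic genome layout with TADs, anchors and AsiSI sites
#'
#' Constructs the structural ground truth for one simulated experiment:
#' chromosomes tiled by TADs, cohesin/CTCF anchor positions at TAD borders
#' plus interior sites, AsiSI recognition sites placed a few kb from randomly
#' chosen anchors under a minimum pairwise spacing, a subset of sites that
#' are actually cut, and the damage (gamma-H2AX) domains around the cuts.
#' Shared nuisance structure (regional background field, trans coverage
#' biases, anchor height jitter) is drawn here once so that treated and
#' untreated simulations share it.
#'
#' Everything is a pure function of the configuration (including its seed).
#'
#' @param config a [sim_config()].
#' @return object of class `dsb_simulation`: list with `layout`, `config`,
#'   `tads`, `anchors`, `dsbs` (all AsiSI sites), and `truth` (cut ids, cut
#'   sites, damaged domains, per-genotype injected effects, nuisance fields).
#' @export
build_layout <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(stream_seed(config, 1L), {
    chroms <- sprintf("chr%d", seq_len(config$n_chrom))
    L <- config$chrom_length
    layout <- genome_layout(chroms, rep(L, config$n_chrom))

    # TADs tile each chromosome; sizes gamma-distributed around the mean.
    tad_rows <- list()
    for (ch in chroms) {
      n_tad <- max(2L, round(L / config$tad_mean_size))
      for (try in 1:200) {
        sizes <- stats::rgamma(n_tad, shape = 8, rate = 8 / config$tad_mean_size)
        sizes <- sizes / sum(sizes) * L
        if (min(sizes) >= 0.25 * config$tad_mean_size) break
      }
      bnd <- round(cumsum(sizes) / 1e4) * 1e4
      bnd[n_tad] <- L
      bnd <- unique(bnd)
      starts <- c(0, utils::head(bnd, -1))
      tad_rows[[ch]] <- data.frame(chrom = ch, start = starts, end = bnd,
                                   stringsAsFactors = FALSE)
    }
    tads <- do.call(rbind, c(tad_rows, make.row.names = FALSE))

    # Anchors: one at each internal TAD border, plus interior anchors.
    anchor_rows <- list()
    for (ch in chroms) {
      tt <- tads[tads$chrom == ch, ]
      border <- tt$start[tt$start > 0]
      interior <- unlist(lapply(seq_len(nrow(tt)), function(i) {
        w <- tt$end[i] - tt$start[i]
        if (config$anchors_per_tad < 1) return(numeric(0))
        round(stats::runif(config$anchors_per_tad,
                           tt$start[i] + 0.15 * w, tt$end[i] - 0.15 * w))
      }))
      pos <- sort(unique(c(border, interior)))
      anchor_rows[[ch]] <- data.frame(chrom = ch, pos = pos,
                                      stringsAsFactors = FALSE)
    }
    anchors <- do.call(rbind, c(anchor_rows, make.row.names = FALSE))
    anchors$id <- sprintf("anchor_%03d", seq_len(nrow(anchors)))
    anchors$height_jitter <- exp(stats::rnorm(nrow(anchors), 0, 0.15))
    anchors$ctcf_offset <- round(stats::runif(nrow(anchors), -100, 100))

    # AsiSI sites: a few kb from a random anchor, >= dsb_min_spacing apart.
    # Placement restarts from scratch when rejection sampling paints itself
    # into a corner, so feasible configurations always succeed.
    margin <- min(1.2e6, L / 6)  # keeps damage domains clear of chromosome ends
    placed <- NULL
    for (restart in 1:50) {
      placed <- data.frame(chrom = character(0), start = numeric(0))
      tries <- 0L
      while (nrow(placed) < config$n_asisi && tries < 500L * config$n_asisi) {
        tries <- tries + 1L
        a <- anchors[sample.int(nrow(anchors), 1), ]
        pos <- a$pos + sample(c(-1, 1), 1) * round(stats::runif(1, 2000, 9000))
        if (pos < margin || pos > L - margin) next
        same <- placed$chrom == a$chrom
        if (any(same) &&
            min(abs(placed$start[same] - pos)) < config$dsb_min_spacing)
          next
        placed <- rbind(placed, data.frame(chrom = a$chrom, start = pos))
      }
      if (nrow(placed) == config$n_asisi) break
    }
    if (nrow(placed) < config$n_asisi)
      stop("build_layout: infeasible AsiSI spacing; reduce n_asisi or ",
           "dsb_min_spacing, or enlarge/add chromosomes")
    placed <- placed[order(match(placed$chrom, chroms), placed$start), ]
    dsbs <- dsb_sites(id = sprintf("asisi_%02d", seq_len(nrow(placed))),
                      chrom = placed$chrom, start = placed$start,
                      end = placed$start + 8, layout = layout)
    cut_idx <- sort(sample.int(config$n_asisi, config$n_cut))
    cuts <- dsbs[cut_idx, , drop = FALSE]
    rownames(cuts) <- NULL

    # Damage (gamma-H2AX) truth domains around each cut, merged if touching.
    hw <- config$chip$gh2ax_halfwidth
    mids <- cut_midpoint(cuts)
    dom <- data.frame(chrom = cuts$chrom,
                      start = pmax(0, mids - hw),
                      end = pmin(L, mids + hw), stringsAsFactors = FALSE)
    dom <- merge_intervals(dom)
    damaged_domains <- damage_domains(dom$chrom, dom$start, dom$end,
                                      kind = "GH2AX", damaged = TRUE,
                                      layout = layout)

    # TAD partition labelled by whether a cut falls inside.
    tad_mid_hit <- vapply(seq_len(nrow(tads)), function(i) {
      sel <- cuts$chrom == tads$chrom[i]
      any(mids[sel] >= tads$start[i] & mids[sel] < tads$end[i])
    }, logical(1))
    tads <- damage_domains(tads$chrom, tads$start, tads$end, kind = "TAD",
                           damaged = tad_mid_hit, layout = layout)

    # Shared nuisance fields.
    seg <- config$chip$bg_segment
    bg_field <- lapply(chroms, function(ch) {
      m <- ceiling(L / seg)
      exp(stats::rnorm(m, 0, config$chip$bg_log_sd) -
            config$chip$bg_log_sd^2 / 2)
    })
    names(bg_field) <- chroms
    tres <- config$hic$trans_resolution
    trans_factors <- lapply(chroms, function(ch) {
      m <- ceiling(L / tres)
      exp(stats::rnorm(m, 0, config$hic$trans_log_sd) -
            config$hic$trans_log_sd^2 / 2)
    })
    names(trans_factors) <- chroms

    # Non-anchor peak positions (CTCF-only / RAD21-only sites).
    rand_pos <- function(n) data.frame(
      chrom = sample(chroms, n, replace = TRUE),
      pos = round(stats::runif(n, 1e4, L - 1e4)))
    ctcf_only <- rand_pos(config$chip$n_ctcf_only)
    rad21_only <- rand_pos(config$chip$n_rad21_only)

    if (config$with_sequence) {
      seqs <- vapply(chroms, function(ch)
        paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
              collapse = ""), character(1))
      for (i in seq_len(nrow(dsbs))) {
        s <- dsbs$start[i]
        substr(seqs[[dsbs$chrom[i]]], s + 1, s + 8) <- "GCGATCGC"
      }
      layout <- genome_layout(chroms, rep(L, config$n_chrom),
                              sequence = seqs)
    }

    structure(list(
      layout = layout, config = config, tads = tads, anchors = anchors,
      dsbs = dsbs,
      truth = list(cut_ids = cuts$id, cuts = cuts,
                   damaged_domains = damaged_domains,
                   anchor_fc = config$chip$anchor_fc,
                   gamma = config$hic$gamma,
                   intra_damage_boost = config$hic$intra_damage_boost,
                   bg_field = bg_field, trans_factors = trans_factors,
                   ctcf_only = ctcf_only, rad21_only = rad21_only)),
      class = "dsb_simulation")
  })
}

#' @export
print.dsb_simulation <- function(x, ...) {
  cat("dsb_simulation: seed", x$config$seed, "-", length(x$layout),
      "chromosome(s),", nrow(x$tads), "TADs,", nrow(x$anchors), "anchors,",
      nrow(x$dsbs), "AsiSI sites (", length(x$truth$cut_ids), "cut )\n")
  invisible(x)
}

# Add a triangular peak of the given height/half-width to a binned vector.
add_peak <- function(v, bin_size, center, height, halfwidth) {
  b0 <- max(0, floor((center - halfwidth) / bin_size))
  b1 <- min(length(v) - 1, floor((center + halfwidth) / bin_size))
  if (b1 < b0) return(v)
  bins <- b0:b1
  mid <- bins * bin_size + bin_size / 2
  v[bins + 1] <- v[bins + 1] + height * pmax(0, 1 - abs(mid - center) / halfwidth)
  v
}

#' Simulate ChIP-seq coverage tracks and peak calls
#'
#' Generates rpkm-like binned tracks for MRE11, RAD21, CTCF and gamma-H2AX
#' under one (genotype, damage) condition, plus RAD21/CTCF peak lists.
#' RAD21 and CTCF peaks sit at the anchors (triangular, 1 kb); under damage,
#' anchor peak heights inside damaged domains are multiplied by the
#' genotype's `anchor_fc`. MRE11 peaks appear only at cut sites under
#' damage; gamma-H2AX forms a plateau over the damaged domains. Per-bin
#' noise is Poisson on the expected signal scaled by the `depth` parameter;
#' the regional background field is shared across conditions.
#'
#' @param sim a [build_layout()] result.
#' @param genotype one of [GENOTYPES].
#' @param damage `"NT"` or `"DSB"`.
#' @param config optional [sim_config()] override (defaults to `sim$config`).
#' @return list with `tracks` (named list of [coverage_track()]s for MRE11,
#'   RAD21, CTCF, GH2AX), `peaks` (RAD21 and CTCF [signal_peaks()] tables),
#'   `genotype`, `damage`.
#' @export
simulate_chip <- function(sim, genotype = "WT", damage = "NT",
                          config = sim$config) {
  check_condition(genotype, damage)
  cp <- config$chip
  layout <- sim$layout
  dmg <- damage == "DSB"
  doms <- sim$truth$damaged_domains
  cut_mids <- cut_midpoint(sim$truth$cuts)

  anchors <- sim$anchors
  in_dom <- point_in_intervals(anchors$chrom, anchors$pos, doms)
  fa <- if (dmg) cp$anchor_fc[[genotype]] else 1
  rad21_scale <- if (genotype == "RAD21-") cp$rad21_depletion else 1
  rad21_height <- cp$baseline_height * anchors$height_jitter * rad21_scale *
    ifelse(in_dom, fa, 1)
  ctcf_height <- cp$baseline_height * anchors$height_jitter

  with_seed(stream_seed(config, 2L, genotype, damage), {
    tracks <- list()
    for (factor_name in c("MRE11", "RAD21", "CTCF", "GH2AX")) {
      vals <- list()
      for (ch in layout$chrom_names) {
        nb <- n_bins(layout, ch, cp$bin_size)
        seg_idx <- pmin(floor(((seq_len(nb) - 1) * cp$bin_size) / cp$bg_segment) + 1,
                        length(sim$truth$bg_field[[ch]]))
        e <- cp$background * sim$truth$bg_field[[ch]][seg_idx]
        sel_a <- which(anchors$chrom == ch)
        if (factor_name == "RAD21") {
          for (k in sel_a)
            e <- add_peak(e, cp$bin_size, anchors$pos[k], rad21_height[k],
                          cp$peak_halfwidth)
          ro <- sim$truth$rad21_only
          for (k in which(ro$chrom == ch))
            e <- add_peak(e, cp$bin_size, ro$pos[k],
                          cp$baseline_height * rad21_scale, cp$peak_halfwidth)
        } else if (factor_name == "CTCF") {
          for (k in sel_a)
            e <- add_peak(e, cp$bin_size, anchors$pos[k] + anchors$ctcf_offset[k],
                          ctcf_height[k], cp$peak_halfwidth)
          co <- sim$truth$ctcf_only
          for (k in which(co$chrom == ch))
            e <- add_peak(e, cp$bin_size, co$pos[k], cp$baseline_height,
                          cp$peak_halfwidth)
        } else if (factor_name == "MRE11" && dmg) {
          for (m in cut_mids[sim$truth$cuts$chrom == ch])
            e <- add_peak(e, cp$bin_size, m, cp$mre11_height,
                          cp$peak_halfwidth)
        } else if (factor_name == "GH2AX" && dmg) {
          dd <- doms[doms$chrom == ch, , drop = FALSE]
          for (i in seq_len(nrow(dd))) {
            b0 <- floor(dd$start[i] / cp$bin_size)
            b1 <- min(nb - 1, floor((dd$end[i] - 1) / cp$bin_size))
            e[(b0:b1) + 1] <- e[(b0:b1) + 1] + cp$gh2ax_height
          }
        }
        vals[[ch]] <- stats::rpois(nb, e * cp$depth) / cp$depth
      }
      tracks[[factor_name]] <- coverage_track(cp$bin_size, vals, layout)
    }

    hw <- cp$peak_halfwidth
    rad21_peaks <- signal_peaks(
      chrom = c(anchors$chrom, sim$truth$rad21_only$chrom),
      start = pmax(0, c(anchors$pos, sim$truth$rad21_only$pos) - hw),
      end = c(anchors$pos, sim$truth$rad21_only$pos) + hw,
      summit = c(anchors$pos, sim$truth$rad21_only$pos),
      signal = c(rad21_height, rep(cp$baseline_height * rad21_scale,
                                   nrow(sim$truth$rad21_only))),
      layout = layout)
    ctcf_pos <- c(anchors$pos + anchors$ctcf_offset, sim$truth$ctcf_only$pos)
    ctcf_peaks <- signal_peaks(
      chrom = c(anchors$chrom, sim$truth$ctcf_only$chrom),
      start = pmax(0, ctcf_pos - hw), end = ctcf_pos + hw,
      summit = ctcf_pos,
      signal = c(ctcf_height, rep(cp$baseline_height,
                                  nrow(sim$truth$ctcf_only))),
      layout = layout)
    ord <- order(match(rad21_peaks$chrom, layout$chrom_names),
                 rad21_peaks$start)
    rad21_peaks <- rad21_peaks[ord, ]; rownames(rad21_peaks) <- NULL
    ord <- order(match(ctcf_peaks$chrom, layout$chrom_names),
                 ctcf_peaks$start)
    ctcf_peaks <- ctcf_peaks[ord, ]; rownames(ctcf_peaks) <- NULL

    list(tracks = tracks,
         peaks = list(RAD21 = rad21_peaks, CTCF = ctcf_peaks),
         genotype = genotype, damage = damage)
  })
}

#' Simulate Hi-C contact matrices
#'
#' Intra-chromosomal matrices follow a power-law distance decay
#' `(d + 1)^-alpha`, multiplied by `tad_boost` when both bins share a TAD
#' (forced to 1 in the damaged `RAD21-` condition, emulating degron
#' depletion concurrent with break induction), by `intra_damage_boost` when
#' both bins lie in the same damaged domain under damage, and by the
#' genotype's `gamma` when the bins lie in two distinct damaged domains
#' under damage. Counts are Poisson draws around the expectation scaled to
#' the configured per-chromosome depth, symmetrized. Inter-chromosomal
#' matrices (at 250 kb by default) are a uniform baseline modulated by
#' per-bin coverage biases and the genotype's `trans_gamma` at
#' damaged-domain bin pairs under damage.
#'
#' @inheritParams simulate_chip
#' @return list with `intra` (named list of [contact_matrix()] per
#'   chromosome), `inter` (named list keyed `"chrA|chrB"`), `genotype`,
#'   `damage`.
#' @export
simulate_contacts <- function(sim, genotype = "WT", damage = "NT",
                              config = sim$config) {
  check_condition(genotype, damage)
  hp <- config$hic
  layout <- sim$layout
  dmg <- damage == "DSB"
  doms <- sim$truth$damaged_domains
  beta <- if (genotype == "RAD21-" && dmg) 1 else hp$tad_boost
  gam <- if (dmg) hp$gamma[[genotype]] else 1
  boost <- if (dmg) hp$intra_damage_boost else 1
  tgam <- if (dmg) hp$trans_gamma[[genotype]] else 1

  # 1-based domain index per bin midpoint (0 = outside), per chromosome.
  dom_index <- function(ch, n, res) {
    mid <- (seq_len(n) - 1) * res + res / 2
    dd <- doms[doms$chrom == ch, , drop = FALSE]
    idx <- integer(n)
    for (i in seq_len(nrow(dd)))
      idx[mid >= dd$start[i] & mid < dd$end[i]] <- i
    idx
  }

  with_seed(stream_seed(config, 3L, genotype, damage), {
    intra <- list()
    for (ch in layout$chrom_names) {
      n <- n_bins(layout, ch, hp$resolution)
      d <- abs(outer(seq_len(n), seq_len(n), "-"))
      E <- (d + 1)^(-hp$alpha)
      tt <- sim$tads[sim$tads$chrom == ch, , drop = FALSE]
      mid <- (seq_len(n) - 1) * hp$resolution + hp$resolution / 2
      tid <- findInterval(mid, tt$start)
      same_tad <- outer(tid, tid, "==")
      E[same_tad] <- E[same_tad] * beta
      if (dmg) {
        di <- dom_index(ch, n, hp$resolution)
        in_dom <- di > 0
        same_dom <- outer(di, di, "==") & outer(in_dom, in_dom, "&")
        diff_dom <- outer(di, di, "!=") & outer(in_dom, in_dom, "&")
        E[same_dom] <- E[same_dom] * boost
        E[diff_dom] <- E[diff_dom] * gam
      }
      ut <- upper.tri(E, diag = TRUE)
      E <- E * (hp$depth / sum(E[ut]))
      M <- matrix(0, n, n)
      M[ut] <- stats::rpois(sum(ut), E[ut])
      M <- M + t(M) - diag(diag(M), n)
      intra[[ch]] <- contact_matrix(ch, ch, hp$resolution, M, layout)
    }

    inter <- list()
    chroms <- layout$chrom_names
    if (length(chroms) > 1) {
      for (ia in 1:(length(chroms) - 1)) for (ib in (ia + 1):length(chroms)) {
        ca <- chroms[ia]; cb <- chroms[ib]
        na <- n_bins(layout, ca, hp$trans_resolution)
        nb_ <- n_bins(layout, cb, hp$trans_resolution)
        E <- hp$trans_baseline *
          outer(sim$truth$trans_factors[[ca]][seq_len(na)],
                sim$truth$trans_factors[[cb]][seq_len(nb_)])
        if (dmg) {
          da <- dom_index(ca, na, hp$trans_resolution) > 0
          db <- dom_index(cb, nb_, hp$trans_resolution) > 0
          pair <- outer(da, db, "&")
          E[pair] <- E[pair] * tgam
        }
        M <- matrix(stats::rpois(na * nb_, E), na, nb_)
        inter[[paste(ca, cb, sep = "|")]] <-
          contact_matrix(ca, cb, hp$trans_resolution, M, layout)
      }
    }
    list(intra = intra, inter = inter, genotype = genotype, damage = damage)
  })
}

# Brute-force microhomology check used internally by the generator so that
# simulated flanks embed exactly the drawn overlap.
mh_brute <- function(bait_flank, prey_flank) {
  kmax <- min(nchar(bait_flank), nchar(prey_flank))
  best <- 0L
  for (k in seq_len(kmax)) {
    suf <- substr(bait_flank, nchar(bait_flank) - k + 1, nchar(bait_flank))
    pre <- substr(prey_flank, 1, k)
    if (suf == pre && !grepl("N", suf)) best <- k
  }
  best
}

#' Simulate an HTGTS junction library
#'
#' Junctions from one bait cut site: a configured fraction are bait-proximal
#' (prey within +/- 20 kb of the bait), a per-genotype fraction land at other
#' cut sites with probability proportional to the bait-prey contact-window
#' score (so translocation frequency tracks contact frequency), and the
#' remainder disperse uniformly over the genome. Microhomology length per
#' junction is geometric; flanking sequences are constructed to embed
#' exactly that overlap.
#'
#' @param sim a [build_layout()] result.
#' @param bait_id id of a cut site (must be in `sim$truth$cut_ids`).
#' @param contacts optional [simulate_contacts()] result used to weight prey
#'   sites by contact frequency; uniform weights when `NULL`.
#' @param genotype one of [GENOTYPES] (selects the translocation rate).
#' @param config optional [sim_config()] override.
#' @return junction data.frame (schema of [read_junctions()]) with extra
#'   ground-truth columns `sim_category` (`bait`, `site`, `background`),
#'   `sim_prey_id` and `sim_mh`.
#' @export
simulate_junctions <- function(sim, bait_id, contacts = NULL,
                               genotype = "WT", config = sim$config) {
  check_condition(genotype, "DSB")
  jp <- config$junction
  if (!bait_id %in% sim$truth$cut_ids)
    stop("simulate_junctions: bait '", bait_id, "' is not a cut site")
  cuts <- sim$truth$cuts
  bait <- cuts[cuts$id == bait_id, ]
  bait_mid <- cut_midpoint(bait)
  preys <- cuts[cuts$id != bait_id, , drop = FALSE]
  prey_mids <- cut_midpoint(preys)
  L <- sim$config$chrom_length

  rate <- jp$translocation_rate[[genotype]]
  p_bg <- 1 - rate - jp$bait_proximal_fraction
  if (p_bg < 0) stop("simulate_junctions: category fractions exceed 1")

  w <- rep(1, nrow(preys))
  if (!is.null(contacts) && nrow(preys)) {
    for (i in seq_len(nrow(preys))) {
      if (preys$chrom[i] == bait$chrom) {
        m <- contacts$intra[[bait$chrom]]
        w[i] <- trans_window_score(m, bait_mid, prey_mids[i], warn = FALSE)
      } else {
        key <- paste(bait$chrom, preys$chrom[i], sep = "|")
        if (!is.null(contacts$inter[[key]])) {
          w[i] <- trans_window_score(contacts$inter[[key]], bait_mid,
                                     prey_mids[i], warn = FALSE)
        } else {
          key <- paste(preys$chrom[i], bait$chrom, sep = "|")
          w[i] <- trans_window_score(contacts$inter[[key]], prey_mids[i],
                                     bait_mid, warn = FALSE)
        }
      }
    }
    if (all(w == 0)) w <- rep(1, nrow(preys))
  }

  with_seed(stream_seed(config, 4L, genotype, "DSB",
                        extra = match(bait_id, sim$dsbs$id)), {
    n <- jp$n_junctions
    category <- sample(c("bait", "site", "background"), n, replace = TRUE,
                       prob = c(jp$bait_proximal_fraction, rate, p_bg))
    if (nrow(preys) == 0) category[category == "site"] <- "background"

    prey_chrom <- character(n); prey_pos <- numeric(n)
    prey_id <- rep(NA_character_, n)
    is_bait <- category == "bait"
    nb <- sum(is_bait)
    prey_chrom[is_bait] <- bait$chrom
    prey_pos[is_bait] <- bait_mid + round(stats::runif(nb, -1.9e4, 1.9e4))
    is_site <- category == "site"
    ns <- sum(is_site)
    if (ns) {
      idx <- sample.int(nrow(preys), ns, replace = TRUE, prob = w)
      prey_chrom[is_site] <- preys$chrom[idx]
      prey_pos[is_site] <- prey_mids[idx] +
        round(stats::rnorm(ns, 0, jp$prey_scatter_sd))
      prey_id[is_site] <- preys$id[idx]
    }
    is_bg <- category == "background"
    ng <- sum(is_bg)
    if (ng) {
      prey_chrom[is_bg] <- sample(sim$layout$chrom_names, ng, replace = TRUE)
      prey_pos[is_bg] <- round(stats::runif(ng, 1e4, L - 1e4))
    }
    prey_pos <- pmin(pmax(prey_pos, 0), L - 1)

    mh <- pmin(stats::rgeom(n, jp$mh_geometric_p), jp$mh_max)
    fl <- jp$flank_length
    bait_flank <- random_dna(n, fl)
    prey_flank <- character(n)
    for (i in seq_len(n)) {
      k <- mh[i]
      core <- if (k > 0) substr(bait_flank[i], fl - k + 1, fl) else ""
      repeat {
        cand <- paste0(core, random_dna(1, fl - k))
        if (mh_brute(bait_flank[i], cand) == k) break
      }
      prey_flank[i] <- cand
    }

    df <- data.frame(
      read_id = sprintf("J%06d", seq_len(n)),
      bait_chrom = bait$chrom, bait_pos = bait_mid,
      bait_strand = "+",
      prey_chrom = prey_chrom, prey_pos = prey_pos,
      prey_strand = sample(c("+", "-"), n, replace = TRUE),
      bait_flank = bait_flank, prey_flank = prey_flank,
      stringsAsFactors = FALSE)
    validate_junctions(df)
    df$sim_category <- category
    df$sim_prey_id <- prey_id
    df$sim_mh <- mh
    df
  })
}
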