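#' Read a pipeline configuration file
#'
#' Flat structured key=value text with `[section]` headers; `#` starts a
#' comment. Values are auto-typed (numeric where possible, TRUE/FALSE for
#' logicals). Returns a named list of sections, each a named list of values.
#'
#' @param path config file path.
#' @return nested named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("read_run_config: file not found: ", path)
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list(); section <- NULL
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (grepl("^\\[.+\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      if (is.null(out[[section]])) out[[section]] <- list()
    } else if (grepl("=", ln, fixed = TRUE)) {
      if (is.null(section))
        stop("read_run_config: key outside any [section] at line ", i)
      key <- trimws(sub("=.*$", "", ln))
      val <- trimws(sub("^[^=]*=", "", ln))
      num <- suppressWarnings(as.numeric(val))
      out[[section]][[key]] <-
        if (!is.na(num)) num
        else if (toupper(val) %in% c("TRUE", "FALSE")) as.logical(val)
        else val
    } else {
      stop("read_run_config: malformed line ", i, ": ", ln)
    }
  }
  out
}

config_to_sim <- function(cfg) {
  sim_keys <- cfg$simulate
  if (is.null(sim_keys))
    stop("run_pipeline: config has no [simulate] section")
  if (is.null(sim_keys$seed))
    stop("run_pipeline: simulation block must name a seed")
  pick <- function(prefix) {
    keys <- names(sim_keys)[startsWith(names(sim_keys), prefix)]
    out <- sim_keys[keys]
    names(out) <- sub(prefix, "", names(out))
    out
  }
  top <- sim_keys[!grepl("^(chip_|hic_|junction_)", names(sim_keys))]
  args <- c(top, list(chip = pick("chip_"), hic = pick("hic_"),
                      junction = pick("junction_")))
  do.call(sim_config, args)
}

write_tsv <- function(df, path) {
  data.table::fwrite(as.data.frame(df), path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Sample separation-matched control domain pairs
#'
#' Picks undamaged domain pairs matched in count and, greedily, in genomic
#' separation to a given set of damaged (DSB-DSB) pairs, for use as the
#' Ctrl-Ctrl comparison set in [inter_domain_pair_fc()]. Seeded for
#' reproducibility.
#'
#' @param control_domains [damage_domains()] data.frame of undamaged domains.
#' @param dsb_pairs list of domain pairs (see [domain_pairs()]).
#' @param seed integer seed for the matching order.
#' @return list of domain pairs, at most `length(dsb_pairs)` of them.
#' @export
control_pairs_matched <- function(control_domains, dsb_pairs, seed) {
  cand <- list()
  for (ch in unique(control_domains$chrom)) {
    sub <- control_domains[control_domains$chrom == ch, , drop = FALSE]
    if (nrow(sub) < 2) next
    idx <- utils::combn(nrow(sub), 2)
    for (k in seq_len(ncol(idx)))
      cand[[length(cand) + 1]] <- list(sub[idx[1, k], ], sub[idx[2, k], ])
  }
  if (!length(cand)) return(list())
  sep <- vapply(cand, function(p) {
    abs((p[[1]]$start + p[[1]]$end) / 2 - (p[[2]]$start + p[[2]]$end) / 2)
  }, numeric(1))
  target <- vapply(dsb_pairs, function(p) {
    abs((p[[1]]$start + p[[1]]$end) / 2 - (p[[2]]$start + p[[2]]$end) / 2)
  }, numeric(1))
  with_seed(seed, {
    taken <- rep(FALSE, length(cand))
    out <- list()
    for (t in sample(target)) {
      free <- which(!taken)
      if (!length(free)) break
      k <- free[which.min(abs(sep[free] - t))]
      taken[k] <- TRUE
      out[[length(out) + 1]] <- cand[[k]]
    }
    out
  })
}

#' All intrachromosomal pairs of a domain set
#'
#' @param domains [damage_domains()] data.frame.
#' @return list of two-element lists of one-row domains.
#' @export
domain_pairs <- function(domains) {
  out <- list()
  for (ch in unique(domains$chrom)) {
    sub <- domains[domains$chrom == ch, , drop = FALSE]
    if (nrow(sub) < 2) next
    idx <- utils::combn(nrow(sub), 2)
    for (k in seq_len(ncol(idx)))
      out[[length(out) + 1]] <- list(sub[idx[1, k], ], sub[idx[2, k], ])
  }
  out
}

#' Run the full analysis pipeline from a config file
#'
#' Executes simulate -> DSB calling -> ChIP enrichment -> Hi-C domain
#' statistics -> junction analytics for the configured genotype, writing all
#' result tables, a parameter/run log and a one-page plain-text summary into
#' `out_dir`. Outputs are deterministic: running the same config twice gives
#' byte-identical files.
#'
#' @param config_path path to a config file (see [read_run_config()]); must
#'   contain a `[simulate]` section with a `seed`. An optional `[run]`
#'   section sets `genotype` (default WT), `min_fc` and `flank` (DSB
#'   calling), and `bait` (cut-site id; default the first cut).
#' @param out_dir output directory (created if needed).
#' @return invisibly, the output directory.
#' @export
run_pipeline <- function(config_path, out_dir) {
  cfg <- read_run_config(config_path)
  config <- config_to_sim(cfg)
  run <- cfg$run
  genotype <- if (!is.null(run$genotype)) run$genotype else "WT"
  min_fc <- if (!is.null(run$min_fc)) run$min_fc else 3
  flank <- if (!is.null(run$flank)) run$flank else 500
  check_condition(genotype, "DSB")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c("breakscape run log",
                 paste0("package_version=",
                        as.character(utils::packageVersion("breakscape"))),
                 paste0("seed=", config$seed),
                 paste0("genotype=", genotype))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # --- simulate -------------------------------------------------------------
  sim <- stage("simulate", build_layout(config))
  chip_nt <- stage("simulate", simulate_chip(sim, genotype, "NT"))
  chip_dsb <- stage("simulate", simulate_chip(sim, genotype, "DSB"))
  hic_nt <- stage("simulate", simulate_contacts(sim, genotype, "NT"))
  hic_dsb <- stage("simulate", simulate_contacts(sim, genotype, "DSB"))
  write_bed(sim$dsbs, file.path(out_dir, "asisi_sites.bed"))
  log_lines <- c(log_lines,
                 paste0("n_asisi=", nrow(sim$dsbs)),
                 paste0("n_cut=", length(sim$truth$cut_ids)))

  # --- dsb-call -------------------------------------------------------------
  called <- stage("dsb-call",
                  call_dsb_sites(chip_dsb$tracks$MRE11, sim$dsbs,
                                 min_fc = min_fc, flank = flank))
  write_bed(data.frame(chrom = called$chrom, start = called$start,
                       end = called$end, name = called$id, score = 0,
                       strand = "."),
            file.path(out_dir, "dsb_calls.bed"))
  log_lines <- c(log_lines, paste0("n_dsb_called=", nrow(called)))

  # --- enrich ---------------------------------------------------------------
  domains <- stage("enrich",
                   call_damage_domains(chip_dsb$tracks$GH2AX,
                                       chip_nt$tracks$GH2AX, dsbs = called))
  write_tsv(domains, file.path(out_dir, "damage_domains.tsv"))
  anchors <- stage("enrich",
                   call_anchor_sites(chip_dsb$peaks$RAD21,
                                     chip_dsb$peaks$CTCF))
  write_tsv(anchors, file.path(out_dir, "anchors.tsv"))
  enr <- stage("enrich",
               category_fold_change(chip_dsb$peaks$RAD21, called,
                                    chip_dsb$tracks$RAD21,
                                    chip_nt$tracks$RAD21))
  write_tsv(enr$table, file.path(out_dir, "enrichment_table.tsv"))
  write_tsv(enr$summary, file.path(out_dir, "enrichment_summary.tsv"))
  ade <- stage("enrich",
               anchor_domain_enrichment(anchors, domains,
                                        chip_dsb$tracks$RAD21,
                                        chip_nt$tracks$RAD21))
  write_tsv(ade$table, file.path(out_dir, "anchor_domain_table.tsv"))
  log_lines <- c(log_lines,
                 paste0("n_domains=", nrow(domains)),
                 paste0("n_anchors=", nrow(anchors)),
                 paste0("anchor_fc_inside=",
                        formatC(ade$mean_fc_inside, digits = 6,
                                format = "g")))

  # --- hic ------------------------------------------------------------------
  ctrl_tads <- sim$tads[!sim$tads$damaged, , drop = FALSE]
  all_domains <- rbind(domains[, c("chrom", "start", "end", "kind", "damaged")],
                       ctrl_tads)
  intra <- stage("hic", intra_domain_fc(hic_dsb$intra, hic_nt$intra,
                                        all_domains))
  write_tsv(intra$per_domain, file.path(out_dir, "intra_domain_fc.tsv"))
  write_tsv(intra$summary, file.path(out_dir, "intra_domain_summary.tsv"))
  dsb_pairs <- domain_pairs(domains[domains$damaged %in% TRUE, , drop = FALSE])
  inter <- NULL
  if (length(dsb_pairs)) {
    ctrl_pairs <- control_pairs_matched(ctrl_tads, dsb_pairs,
                                        seed = config$seed + 77L)
    pairs <- c(dsb_pairs, ctrl_pairs)
    labels <- c(rep("DSB-DSB", length(dsb_pairs)),
                rep("Ctrl-Ctrl", length(ctrl_pairs)))
    inter <- stage("hic", inter_domain_pair_fc(hic_dsb$intra, hic_nt$intra,
                                               pairs, labels))
    write_tsv(inter$per_pair, file.path(out_dir, "inter_domain_pairs.tsv"))
    write_tsv(inter$summary, file.path(out_dir, "inter_domain_summary.tsv"))
  }
  if (nrow(called)) {
    vp_chrom <- called$chrom[1]
    res <- config$hic$resolution
    vp <- stage("hic", viewpoint_track(hic_dsb$intra[[vp_chrom]],
                                       hic_nt$intra[[vp_chrom]],
                                       pos_to_bin(cut_midpoint(called)[1],
                                                  res)))
    vp_out <- data.frame(chrom = vp_chrom, start = vp$start,
                         end = pmin(vp$start + res,
                                    sim$layout$chrom_lengths[[vp_chrom]]),
                         log2fc = vp$log2fc)
    write_tsv(vp_out, file.path(out_dir, "viewpoint.bedgraph.tsv"))
  }
  cuts <- sim$truth$cuts
  trans_rows <- list()
  for (i in seq_len(nrow(cuts))) for (j in seq_len(nrow(cuts))) {
    if (i >= j || cuts$chrom[i] == cuts$chrom[j]) next
    key <- paste(cuts$chrom[i], cuts$chrom[j], sep = "|")
    if (is.null(hic_dsb$inter[[key]])) next
    st <- trans_window_score(hic_dsb$inter[[key]], cut_midpoint(cuts[i, ]),
                             cut_midpoint(cuts[j, ]))
    su <- trans_window_score(hic_nt$inter[[key]], cut_midpoint(cuts[i, ]),
                             cut_midpoint(cuts[j, ]))
    trans_rows[[length(trans_rows) + 1]] <- data.frame(
      site_a = cuts$id[i], site_b = cuts$id[j], sum_treated = st,
      sum_untreated = su, log2fc = trans_window_log2fc(st, su))
  }
  trans_tab <- if (length(trans_rows))
    do.call(rbind, c(trans_rows, make.row.names = FALSE)) else
    data.frame(site_a = character(0), site_b = character(0),
               sum_treated = numeric(0), sum_untreated = numeric(0),
               log2fc = numeric(0))
  write_tsv(trans_tab, file.path(out_dir, "trans_window_scores.tsv"))

  # --- junctions ------------------------------------------------------------
  bait_id <- if (!is.null(run$bait)) run$bait else sim$truth$cut_ids[1]
  jx <- stage("junctions",
              simulate_junctions(sim, bait_id, contacts = hic_dsb,
                                 genotype = genotype))
  bait <- cuts[cuts$id == bait_id, ]
  bait$pos <- cut_midpoint(bait)
  ann <- stage("junctions", annotate_junctions(jx, bait, called, domains))
  write_tsv(ann$records, file.path(out_dir, "junctions_labelled.tsv"))
  write_tsv(as.data.frame(ann$class_counts),
            file.path(out_dir, "junction_class_counts.tsv"))
  bins <- bin_junction_counts(ann$records)
  write_tsv(bins, file.path(out_dir, "junction_bins.tsv"))
  mh <- mh_profile(ann$records$mh_len)
  write_tsv(mh$histogram, file.path(out_dir, "mh_histogram.tsv"))
  log_lines <- c(log_lines,
                 paste0("n_junctions_kept=", nrow(ann$records)),
                 paste0("n_junctions_bait_proximal=", nrow(ann$removed)),
                 paste0("mean_mh=", formatC(mh$mean_mh, digits = 6,
                                            format = "g")))

  # --- report ---------------------------------------------------------------
  fmt <- function(x) formatC(x, digits = 4, format = "f")
  sm <- enr$summary
  summary_lines <- c(
    "breakscape summary", "==================", "",
    paste0("Genotype: ", genotype, "   seed: ", config$seed), "",
    "RAD21 enrichment by distance to DSB (treated/untreated, pc 0.1):",
    sprintf("  %-6s n=%-5d mean FC=%s %s", sm$category, sm$n,
            fmt(sm$mean_fc), sm$stars), "",
    sprintf("Anchor FC inside damaged domains:  %s (n=%d)",
            fmt(ade$mean_fc_inside), ade$n_inside),
    sprintf("Anchor FC outside damaged domains: %s (n=%d) %s",
            fmt(ade$mean_fc_outside), ade$n_outside,
            if (!is.null(ade$test))
              paste0("p=", format(ade$test$p_value, digits = 3), " ",
                     significance_stars(ade$test$p_value)) else ""), "",
    "Intra-domain Hi-C fold change (O/E):",
    sprintf("  %-8s n=%-5d mean FC=%s", intra$summary$group,
            intra$summary$n, fmt(intra$summary$mean_fc)))
  if (!is.null(inter))
    summary_lines <- c(summary_lines, "",
                       "Inter-domain pair fold change (O/E):",
                       sprintf("  %-9s n=%-4d mean FC=%s",
                               inter$summary$label, inter$summary$n,
                               fmt(inter$summary$mean_fc)))
  summary_lines <- c(summary_lines, "",
                     sprintf("Junctions: %d kept (%d cis-deletions, %d translocations), %d bait-proximal removed",
                             nrow(ann$records),
                             ann$class_counts[["cis_deletion"]],
                             ann$class_counts[["translocation"]],
                             nrow(ann$removed)),
                     sprintf("Microhomology: mean %s, fraction >=1: %s",
                             fmt(mh$mean_mh), fmt(mh$fraction_mh)))
  writeLines(summary_lines, file.path(out_dir, "summary.txt"))
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}
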