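#' Call DSB sites from an MRE11-like coverage track
#'
#' A candidate cut site is called when the mean signal in a +/- `flank`
#' window around its cut midpoint exceeds `min_fc` times the local
#' background, taken as the median of a +/- `10 * flank` window with the
#' core excluded. `min_fc = 0` returns the candidates unchanged.
#'
#' @param mre11_track a [coverage_track()].
#' @param candidates [dsb_sites()] data.frame on the same layout.
#' @param min_fc minimum signal/background ratio (default 3).
#' @param flank core half-width in bp (default 500; must be >= bin size).
#' @return the called subset of `candidates`, sorted by position.
#' @export
call_dsb_sites <- function(mre11_track, candidates, min_fc = 3, flank = 500) {
  if (min_fc < 0) stop("call_dsb_sites: min_fc must be >= 0")
  if (flank < mre11_track$bin_size)
    stop("call_dsb_sites: flank (", flank, ") smaller than track bin size (",
         mre11_track$bin_size, ")")
  if (nrow(candidates) == 0) return(candidates)
  bs <- mre11_track$bin_size
  mids <- cut_midpoint(candidates)
  called <- logical(nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    v <- mre11_track$values[[candidates$chrom[i]]]
    if (is.null(v)) stop("call_dsb_sites: unknown chromosome ",
                         candidates$chrom[i])
    nb <- length(v)
    core <- max(0, floor((mids[i] - flank) / bs)):
      min(nb - 1, floor((mids[i] + flank - 1) / bs))
    wide <- max(0, floor((mids[i] - 10 * flank) / bs)):
      min(nb - 1, floor((mids[i] + 10 * flank - 1) / bs))
    bg_bins <- setdiff(wide, core)
    bg <- if (length(bg_bins)) stats::median(v[bg_bins + 1]) else 0
    # sparse-background degeneracy: a zero median makes the ratio test
    # trigger on any noise, so fall back to the window mean
    if (bg == 0 && length(bg_bins)) bg <- mean(v[bg_bins + 1])
    called[i] <- min_fc == 0 || mean(v[core + 1]) > min_fc * bg
  }
  out <- candidates[called, , drop = FALSE]
  out <- out[order(match(out$chrom, names(mre11_track$values)), out$start), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify peaks by distance to the nearest DSB
#'
#' Distance shells around breaks: `D10K` (d <= 10 kb), `D250K`
#' (10 kb < d <= 250 kb), `D1M` (250 kb < d <= 1 Mb), `CTRL` (> 1 Mb,
#' including peaks on DSB-free chromosomes). Bounds are inclusive; with
#' `cumulative = TRUE` the categories are nested instead of disjoint shells
#' (a D10K peak is then also counted in D250K and D1M summaries downstream).
#'
#' @param peaks [signal_peaks()] data.frame.
#' @param dsbs non-empty [dsb_sites()] data.frame.
#' @return character vector of categories, one per peak (always the finest
#'   shell; nesting is applied by [category_fold_change()]).
#' @export
classify_peak_distance <- function(peaks, dsbs) {
  if (nrow(dsbs) == 0) stop("classify_peak_distance: empty DSB list")
  vapply(seq_len(nrow(peaks)), function(i) {
    same <- dsbs[dsbs$chrom == peaks$chrom[i], , drop = FALSE]
    d <- if (nrow(same)) min_distance(peaks$summit[i], same) else Inf
    if (d <= 1e4) "D10K"
    else if (d <= 2.5e5) "D250K"
    else if (d <= 1e6) "D1M"
    else "CTRL"
  }, character(1))
}

# Per-unit fold change with the ChIP pseudocount.
chip_fc <- function(signal_treated, signal_untreated, eps = 0.1) {
  (signal_treated + eps) / (signal_untreated + eps)
}

enrichment_rows <- function(units, category, treated, untreated, eps = 0.1) {
  st <- interval_mean(treated, units$chrom, units$start, units$end)
  su <- interval_mean(untreated, units$chrom, units$start, units$end)
  data.frame(unit = seq_len(nrow(units)), chrom = units$chrom,
             start = units$start, end = units$end, category = category,
             signal_treated = st, signal_untreated = su,
             fold_change = chip_fc(st, su, eps), stringsAsFactors = FALSE)
}

#' Distance-shell enrichment fold changes
#'
#' Per-peak signal is the mean per-bp value over the peak interval in each
#' track; fold change uses the 0.1 pseudocount. The summary reports the mean
#' FC per distance category and a one-tailed Welch test of each category's
#' FCs against the CTRL category's.
#'
#' @param peaks [signal_peaks()] data.frame.
#' @param dsbs [dsb_sites()] data.frame.
#' @param treated,untreated [coverage_track()]s on a shared bin grid.
#' @param eps pseudocount (default 0.1).
#' @param cumulative treat categories as nested (d <= bound) rather than
#'   disjoint shells.
#' @return list: `table` (per-peak EnrichmentTable rows) and `summary`
#'   (category, n, mean_fc, p_vs_ctrl, stars).
#' @export
category_fold_change <- function(peaks, dsbs, treated, untreated, eps = 0.1,
                                 cumulative = FALSE) {
  if (treated$bin_size != untreated$bin_size)
    stop("category_fold_change: tracks must share a bin grid")
  cat_fine <- classify_peak_distance(peaks, dsbs)
  tab <- enrichment_rows(peaks, cat_fine, treated, untreated, eps)
  shells <- c("D10K", "D250K", "D1M", "CTRL")
  members <- function(cat) {
    if (!cumulative || cat == "CTRL") tab$fold_change[tab$category == cat]
    else switch(cat,
      D10K = tab$fold_change[tab$category == "D10K"],
      D250K = tab$fold_change[tab$category %in% c("D10K", "D250K")],
      D1M = tab$fold_change[tab$category %in% c("D10K", "D250K", "D1M")])
  }
  ctrl <- members("CTRL")
  summary <- do.call(rbind, lapply(shells, function(cat) {
    fcs <- members(cat)
    p <- if (cat != "CTRL" && length(fcs) >= 2 && length(ctrl) >= 2)
      tryCatch(welch_t(fcs, ctrl, tails = "one")$p_value,
               error = function(e) NA_real_) else NA_real_
    data.frame(category = cat, n = length(fcs),
               mean_fc = if (length(fcs)) mean(fcs) else NA_real_,
               p_vs_ctrl = p,
               stars = ifelse(is.na(p), "", significance_stars(p)),
               stringsAsFactors = FALSE)
  }))
  list(table = tab, summary = summary)
}

#' Call cohesin anchor sites by RAD21/CTCF colocalization
#'
#' An anchor is a RAD21 peak whose summit lies within `max_center_gap` of
#' some CTCF peak summit on the same chromosome. Each RAD21 peak is reported
#' at most once.
#'
#' @param rad21_peaks,ctcf_peaks [signal_peaks()] data.frames, sorted.
#' @param max_center_gap maximum summit gap in bp (default 500).
#' @return the anchor subset of `rad21_peaks`.
#' @export
call_anchor_sites <- function(rad21_peaks, ctcf_peaks, max_center_gap = 500) {
  keep <- logical(nrow(rad21_peaks))
  for (ch in unique(rad21_peaks$chrom)) {
    ri <- which(rad21_peaks$chrom == ch)
    cs <- sort(ctcf_peaks$summit[ctcf_peaks$chrom == ch])
    if (!length(cs)) next
    for (i in ri) {
      s <- rad21_peaks$summit[i]
      k <- findInterval(s, cs)
      d <- min(if (k >= 1) abs(s - cs[k]) else Inf,
               if (k < length(cs)) abs(cs[k + 1] - s) else Inf)
      keep[i] <- d <= max_center_gap
    }
  }
  out <- rad21_peaks[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call damage (gamma-H2AX) domains from treated/untreated tracks
#'
#' Tracks are aggregated to `window`-sized bins; the per-bin statistic is
#' `z = (treated - untreated) / sd(untreated)` with the sd taken over the
#' chromosome. Maximal runs of `z > z_lo` containing at least one seed bin
#' (`z > z_hi`) become domains; domains closer than `merge_gap` are merged
#' and domains shorter than `min_width` dropped. With `dsbs` supplied, each
#' domain is flagged damaged when it contains a cut midpoint.
#'
#' @param gh2ax_treated,gh2ax_untreated [coverage_track()]s, shared grid.
#' @param z_hi,z_lo seed and extension thresholds (defaults 2 and 1).
#' @param merge_gap,min_width bp (defaults 100 kb each).
#' @param window aggregation window in bp (default 10 kb).
#' @param dsbs optional called [dsb_sites()] for the damaged flag.
#' @return [damage_domains()] data.frame (kind `GH2AX`).
#' @export
call_damage_domains <- function(gh2ax_treated, gh2ax_untreated,
                                z_hi = 2, z_lo = 1,
                                merge_gap = 1e5, min_width = 1e5,
                                window = 1e4, dsbs = NULL) {
  if (gh2ax_treated$bin_size != gh2ax_untreated$bin_size)
    stop("call_damage_domains: tracks must share a bin grid")
  fac <- max(1, round(window / gh2ax_treated$bin_size))
  t_agg <- aggregate_track(gh2ax_treated, fac)
  u_agg <- aggregate_track(gh2ax_untreated, fac)
  bs <- t_agg$bin_size
  rows <- list()
  for (ch in names(t_agg$values)) {
    tv <- t_agg$values[[ch]]; uv <- u_agg$values[[ch]]
    s <- stats::sd(uv)
    if (is.na(s) || s == 0)
      stop("call_damage_domains: sd of untreated track is 0 on ", ch,
           "; the statistic is undefined on noiseless input")
    z <- (tv - uv) / s
    above <- z > z_lo
    r <- rle(above)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    for (k in which(r$values)) {
      if (!any(z[starts[k]:ends[k]] > z_hi)) next
      rows[[length(rows) + 1]] <- data.frame(
        chrom = ch, start = (starts[k] - 1) * bs,
        end = min(ends[k] * bs, t_agg$layout$chrom_lengths[[ch]]),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(damage_domains(character(0), numeric(0), numeric(0)))
  dom <- do.call(rbind, rows)
  # merge domains separated by less than merge_gap, then size-filter
  dom2 <- dom
  dom2$end <- dom2$end + merge_gap / 2
  dom2$start <- pmax(0, dom2$start - merge_gap / 2)
  merged <- merge_intervals(dom2)
  merged$start <- pmin(merged$start + merge_gap / 2, merged$end)
  merged$end <- merged$end - merge_gap / 2
  merged <- merged[merged$end - merged$start >= min_width, , drop = FALSE]
  if (!nrow(merged))
    return(damage_domains(character(0), numeric(0), numeric(0)))
  damaged <- if (is.null(dsbs)) NA else
    vapply(seq_len(nrow(merged)), function(i) {
      sel <- dsbs$chrom == merged$chrom[i]
      any(cut_midpoint(dsbs[sel, , drop = FALSE]) >= merged$start[i] &
            cut_midpoint(dsbs[sel, , drop = FALSE]) < merged$end[i])
    }, logical(1))
  damage_domains(merged$chrom, merged$start, merged$end, kind = "GH2AX",
                 damaged = damaged, layout = gh2ax_treated$layout)
}

#' Anchor enrichment inside versus outside damaged domains
#'
#' Labels each anchor by whether its summit lies inside a damaged domain,
#' computes per-anchor fold changes (0.1 pseudocount) and compares inside
#' against outside with a one-tailed Welch test (alternative inside >
#' outside).
#'
#' @param anchors [signal_peaks()] data.frame (from [call_anchor_sites()]).
#' @param domains [damage_domains()] data.frame; only `damaged == TRUE` rows
#'   define "inside".
#' @param treated,untreated [coverage_track()]s.
#' @param eps pseudocount.
#' @return list: `table` (per-anchor rows with side label), `mean_fc_inside`,
#'   `mean_fc_outside`, `n_inside`, `n_outside`, `test` (NULL when a side
#'   has fewer than 2 anchors).
#' @export
anchor_domain_enrichment <- function(anchors, domains, treated, untreated,
                                     eps = 0.1) {
  dd <- domains[domains$damaged %in% TRUE, , drop = FALSE]
  inside <- point_in_intervals(anchors$chrom, anchors$summit, dd)
  tab <- enrichment_rows(anchors, ifelse(inside, "inside", "outside"),
                         treated, untreated, eps)
  fi <- tab$fold_change[inside]; fo <- tab$fold_change[!inside]
  test <- if (length(fi) >= 2 && length(fo) >= 2)
    tryCatch(welch_t(fi, fo, tails = "one"), error = function(e) NULL)
    else NULL
  list(table = tab,
       mean_fc_inside = if (length(fi)) mean(fi) else NA_real_,
       mean_fc_outside = if (length(fo)) mean(fo) else NA_real_,
       n_inside = length(fi), n_outside = length(fo), test = test)
}
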