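#' Remove bait-proximal junctions
#'
#' Junctions whose prey lies on the bait chromosome within +/- `window` of
#' the bait position are annotated as bait-site artefacts and removed from
#' translocation analysis; the partition is exact.
#'
#' @param records junction data.frame ([read_junctions()] schema).
#' @param bait one-row [dsb_sites()] data.frame or a list with `chrom` and
#'   `pos`.
#' @param window half-width in bp (default 20,000).
#' @return list: `kept`, `removed`.
#' @export
filter_bait_proximal <- function(records, bait, window = 2e4) {
  bait_chrom <- bait$chrom[1]
  bait_pos <- if (!is.null(bait$pos)) bait$pos[1] else cut_midpoint(bait)[1]
  prox <- records$prey_chrom == bait_chrom &
    abs(records$prey_pos - bait_pos) <= window
  list(kept = records[!prox, , drop = FALSE],
       removed = records[prox, , drop = FALSE])
}

#' Classify junctions as cis-deletions or translocations
#'
#' Cis-deletion iff the prey chromosome equals the bait chromosome;
#' translocation otherwise. Apply after [filter_bait_proximal()].
#'
#' @param records junction data.frame.
#' @param bait as in [filter_bait_proximal()].
#' @return character vector, `"cis_deletion"` or `"translocation"`.
#' @export
classify_cis_trans <- function(records, bait) {
  ifelse(records$prey_chrom == bait$chrom[1], "cis_deletion", "translocation")
}

#' Assign a damage context to each junction
#'
#' `break_site` if the prey lies within +/- `break_window` of any cut
#' midpoint; else `gh2ax_domain` if it lies inside a damaged domain; else
#' `outside`. Precedence is fixed in that order.
#'
#' @param records junction data.frame.
#' @param dsbs [dsb_sites()] data.frame.
#' @param domains [damage_domains()] data.frame (damaged rows define the
#'   domain context).
#' @param break_window half-width in bp (default 2,500).
#' @return character vector of contexts.
#' @export
assign_damage_context <- function(records, dsbs, domains,
                                  break_window = 2500) {
  dd <- domains[domains$damaged %in% TRUE, , drop = FALSE]
  vapply(seq_len(nrow(records)), function(i) {
    ch <- records$prey_chrom[i]; p <- records$prey_pos[i]
    same <- dsbs[dsbs$chrom == ch, , drop = FALSE]
    if (nrow(same) && min_distance(p, same) <= break_window)
      return("break_site")
    if (point_in_intervals(ch, p, dd)) return("gh2ax_domain")
    "outside"
  }, character(1))
}

#' Microhomology length at a junction
#'
#' Largest `k` such that the last `k` bases of the bait flank equal the
#' first `k` bases of the prey flank; `N` never matches.
#'
#' @param bait_flank,prey_flank non-empty uppercase DNA strings (vectors
#'   allowed; recycled pairwise).
#' @return integer vector of microhomology lengths.
#' @export
microhomology_length <- function(bait_flank, prey_flank) {
  if (any(bait_flank == "") || any(prey_flank == ""))
    stop("microhomology_length: empty flank")
  n <- max(length(bait_flank), length(prey_flank))
  bait_flank <- rep_len(bait_flank, n)
  prey_flank <- rep_len(prey_flank, n)
  vapply(seq_len(n), function(i) {
    b <- bait_flank[i]; p <- prey_flank[i]
    lb <- nchar(b); lp <- nchar(p)
    kmax <- min(lb, lp)
    best <- 0L
    # compare from the longest suffix down; the first full match wins
    for (k in kmax:1) {
      suf <- substr(b, lb - k + 1, lb)
      if (!grepl("N", suf, fixed = TRUE) &&
          suf == substr(p, 1, k)) { best <- k; break }
    }
    best
  }, integer(1))
}

#' Junction distance in kbp
#'
#' `floor(|pos_a - pos_b| / 1000)` for two positions on one chromosome.
#'
#' @param pos_a,pos_b bp positions.
#' @param chrom_a,chrom_b optional chromosome names; an error is raised when
#'   they differ.
#' @return integer kbp distance.
#' @export
junction_distance_kbp <- function(pos_a, pos_b, chrom_a = NULL,
                                  chrom_b = NULL) {
  if (!is.null(chrom_a) && !is.null(chrom_b) && any(chrom_a != chrom_b))
    stop("junction_distance_kbp: positions on different chromosomes")
  as.integer(floor(abs(pos_a - pos_b) / 1000))
}

#' Bin unique junction events
#'
#' Deduplicates records by (prey chromosome, position, strand) and counts
#' unique events per `bin`-sized window per chromosome.
#'
#' @param records junction data.frame.
#' @param bin bin width in bp (default 1,000).
#' @return data.frame: chrom, bin_start, count.
#' @export
bin_junction_counts <- function(records, bin = 1000) {
  if (nrow(records) == 0)
    return(data.frame(chrom = character(0), bin_start = numeric(0),
                      count = integer(0)))
  key <- paste(records$prey_chrom, records$prey_pos, records$prey_strand)
  uniq <- records[!duplicated(key), , drop = FALSE]
  bin_start <- floor(uniq$prey_pos / bin) * bin
  agg <- stats::aggregate(list(count = rep(1L, nrow(uniq))),
                          by = list(chrom = uniq$prey_chrom,
                                    bin_start = bin_start), FUN = sum)
  agg <- agg[order(agg$chrom, agg$bin_start), ]
  rownames(agg) <- NULL
  agg
}

#' Condition fold change of junction counts
#'
#' Normalizes per-site counts to library size (events per 10,000 junctions),
#' then reports per-site and aggregate fold changes with a 0.1 pseudocount
#' on the normalized values: `FC = (norm_a + 0.1) / (norm_b + 0.1)`.
#'
#' @param counts_a,counts_b data.frames with columns `site` and `count`
#'   (e.g. unique-event counts per prey site); sites are matched by name and
#'   missing sites count 0.
#' @param total_a,total_b library sizes (> 0).
#' @return list: `per_site` data.frame (site, norm_a, norm_b, fc),
#'   `aggregate_fc`.
#' @export
condition_fold_change <- function(counts_a, counts_b, total_a, total_b) {
  if (total_a <= 0 || total_b <= 0)
    stop("condition_fold_change: zero library total")
  sites <- union(counts_a$site, counts_b$site)
  ca <- counts_a$count[match(sites, counts_a$site)]
  cb <- counts_b$count[match(sites, counts_b$site)]
  ca[is.na(ca)] <- 0; cb[is.na(cb)] <- 0
  norm_a <- ca / total_a * 1e4
  norm_b <- cb / total_b * 1e4
  eps <- 0.1
  per_site <- data.frame(site = sites, norm_a = norm_a, norm_b = norm_b,
                         fc = (norm_a + eps) / (norm_b + eps),
                         stringsAsFactors = FALSE)
  aggregate_fc <- (sum(norm_a) + eps) / (sum(norm_b) + eps)
  list(per_site = per_site, aggregate_fc = aggregate_fc)
}

#' Microhomology usage profile
#'
#' Histogram of per-junction microhomology lengths (per-integer bins from 0
#' to the observed maximum) with summary statistics.
#'
#' @param mh_len integer vector of microhomology lengths (e.g. from
#'   [microhomology_length()]).
#' @return list: `histogram` data.frame (mh_len, count), `fraction_mh` (share
#'   of junctions with mh >= 1), `mean_mh`, `n`.
#' @export
mh_profile <- function(mh_len) {
  n <- length(mh_len)
  lev <- 0:max(0, mh_len)
  counts <- vapply(lev, function(k) sum(mh_len == k), integer(1))
  list(histogram = data.frame(mh_len = lev, count = counts),
       fraction_mh = if (n) mean(mh_len >= 1) else NA_real_,
       mean_mh = if (n) mean(mh_len) else NA_real_,
       n = n)
}

#' Label a junction call set
#'
#' Convenience wrapper running the full junction annotation chain: bait
#' filtering, cis/trans classification, damage-context assignment and
#' microhomology computation.
#'
#' @param records junction data.frame.
#' @param bait one-row bait site (see [filter_bait_proximal()]).
#' @param dsbs,domains see [assign_damage_context()].
#' @param bait_window,break_window windows in bp.
#' @return list: `records` (kept records with `class`, `context`, `mh_len`
#'   columns), `removed` (bait-proximal records), `class_counts`.
#' @export
annotate_junctions <- function(records, bait, dsbs, domains,
                               bait_window = 2e4, break_window = 2500) {
  parts <- filter_bait_proximal(records, bait, bait_window)
  kept <- parts$kept
  if (nrow(kept)) {
    kept$class <- classify_cis_trans(kept, bait)
    kept$context <- assign_damage_context(kept, dsbs, domains, break_window)
    kept$mh_len <- microhomology_length(kept$bait_flank, kept$prey_flank)
  } else {
    kept$class <- character(0); kept$context <- character(0)
    kept$mh_len <- integer(0)
  }
  list(records = kept, removed = parts$removed,
       class_counts = table(factor(kept$class,
                                   levels = c("cis_deletion",
                                              "translocation"))))
}
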