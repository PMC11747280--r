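#' Expected contact profile by distance
#'
#' For an intra-chromosomal matrix, entry `d` (0-based distance in bins) is
#' the raw mean of `counts[i, i + d]` over all valid `i`, zeros included.
#' This is the E of O/E normalization.
#'
#' @param m intra-chromosomal [contact_matrix()].
#' @return numeric vector of length `n_bins` (distances 0 .. n - 1).
#' @export
expected_profile <- function(m) {
  if (!is_intra(m))
    stop("expected_profile: inter-chromosomal input")
  cm <- m$counts
  n <- nrow(cm)
  vapply(0:(n - 1), function(d) {
    i <- seq_len(n - d)
    mean(cm[cbind(i, i + d)])
  }, numeric(1))
}

#' Observed/expected normalization
#'
#' Divides each entry by the mean contact at the same bin separation,
#' removing distance decay. Entries at separations with zero expected value
#' are masked as `NA`.
#'
#' @param m intra-chromosomal [contact_matrix()].
#' @return a [contact_matrix()] of O/E values (symmetric, possibly with NAs).
#' @export
oe_normalize <- function(m) {
  prof <- expected_profile(m)
  n <- nrow(m$counts)
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  E <- matrix(prof[d + 1], n, n)
  oe <- m$counts / E
  oe[E == 0] <- NA_real_
  out <- m
  out$counts <- oe
  out
}

# Bins (1-based) fully contained in [start, end) at the given resolution.
bins_in_interval <- function(start, end, resolution, n) {
  b0 <- ceiling(start / resolution)
  b1 <- floor(end / resolution) - 1
  if (b1 >= n) b1 <- n - 1
  if (b1 < b0) return(integer(0))
  (b0:b1) + 1L
}

#' Mean O/E over bin pairs within one domain
#'
#' Averages O/E over unordered bin pairs (i < j) with both bins fully inside
#' the domain. The main diagonal is excluded by default (self-bin signal is
#' dominated by technical artefacts); masked entries are skipped.
#'
#' @param oe an O/E [contact_matrix()] (intra-chromosomal).
#' @param domain one-row domain data.frame (chrom, start, end).
#' @param include_diagonal include i == j pairs.
#' @return list: `score` (mean O/E), `n_pairs` contributing.
#' @export
intra_domain_score <- function(oe, domain, include_diagonal = FALSE) {
  stopifnot(is_intra(oe))
  if (domain$chrom[1] != oe$chrom_a)
    stop("intra_domain_score: domain is on ", domain$chrom[1],
         ", matrix on ", oe$chrom_a)
  bins <- bins_in_interval(domain$start[1], domain$end[1], oe$resolution,
                           nrow(oe$counts))
  if (length(bins) < 2)
    stop("intra_domain_score: domain spans fewer than 2 bins; ",
         "score undefined")
  sub <- oe$counts[bins, bins, drop = FALSE]
  keep <- upper.tri(sub, diag = include_diagonal)
  vals <- sub[keep]
  vals <- vals[!is.na(vals)]
  if (!length(vals))
    stop("intra_domain_score: all entries masked; score undefined")
  list(score = mean(vals), n_pairs = length(vals))
}

#' Per-domain intra-domain fold changes between two conditions
#'
#' O/E-normalizes both matrices, scores each domain in each, and reports
#' `FC = score_treated / score_untreated` per domain. Domains whose score is
#' undefined in either condition are dropped (and counted). Summaries: mean
#' FC per group (damaged / control), a one-tailed paired t of the damaged
#' group's FCs against 1, and a one-tailed Welch comparison of damaged vs
#' control FCs.
#'
#' @param treated,untreated intra-chromosomal [contact_matrix()] or named
#'   list thereof (keyed by chromosome), same resolution and layout.
#' @param domains [damage_domains()] data.frame.
#' @param include_diagonal passed to [intra_domain_score()].
#' @return list: `per_domain` data.frame (chrom, start, end, damaged,
#'   score_treated, score_untreated, fc), `summary` data.frame per group,
#'   `test_vs_1` (paired t of damaged FCs vs 1, NULL if < 2 domains),
#'   `test_damaged_vs_control` (Welch, NULL if a group has < 2),
#'   `n_dropped`.
#' @export
intra_domain_fc <- function(treated, untreated, domains,
                            include_diagonal = FALSE) {
  treated <- as_matrix_list(treated)
  untreated <- as_matrix_list(untreated)
  oe_t <- lapply(treated, oe_normalize)
  oe_u <- lapply(untreated, oe_normalize)
  rows <- list(); dropped <- 0L
  for (i in seq_len(nrow(domains))) {
    ch <- domains$chrom[i]
    if (is.null(oe_t[[ch]]) || is.null(oe_u[[ch]])) { dropped <- dropped + 1L; next }
    st <- tryCatch(intra_domain_score(oe_t[[ch]], domains[i, ],
                                      include_diagonal),
                   error = function(e) NULL)
    su <- tryCatch(intra_domain_score(oe_u[[ch]], domains[i, ],
                                      include_diagonal),
                   error = function(e) NULL)
    if (is.null(st) || is.null(su) || su$score == 0) {
      dropped <- dropped + 1L
      next
    }
    rows[[length(rows) + 1]] <- data.frame(
      chrom = ch, start = domains$start[i], end = domains$end[i],
      damaged = domains$damaged[i],
      score_treated = st$score, score_untreated = su$score,
      fc = st$score / su$score, stringsAsFactors = FALSE)
  }
  per_domain <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE))
    else data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
                    damaged = logical(0), score_treated = numeric(0),
                    score_untreated = numeric(0), fc = numeric(0))
  grp <- function(d) per_domain$fc[per_domain$damaged == d]
  summary <- data.frame(
    group = c("damaged", "control"),
    n = c(length(grp(TRUE)), length(grp(FALSE))),
    mean_fc = c(mean(grp(TRUE)), mean(grp(FALSE))))
  test_vs_1 <- if (length(grp(TRUE)) >= 2 && stats::sd(grp(TRUE)) > 0)
    paired_t(grp(TRUE), rep(1, length(grp(TRUE))), tails = "one") else NULL
  test_dc <- if (length(grp(TRUE)) >= 2 && length(grp(FALSE)) >= 2)
    tryCatch(welch_t(grp(TRUE), grp(FALSE), tails = "one"),
             error = function(e) NULL) else NULL
  list(per_domain = per_domain, summary = summary, test_vs_1 = test_vs_1,
       test_damaged_vs_control = test_dc, n_dropped = dropped)
}

as_matrix_list <- function(x) {
  if (inherits(x, "contact_matrix")) {
    out <- list(x); names(out) <- x$chrom_a; return(out)
  }
  x
}

#' Mean O/E over the cross rectangle between two domains
#'
#' @param oe intra-chromosomal O/E [contact_matrix()].
#' @param domain_a,domain_b one-row domain data.frames on the matrix
#'   chromosome; must not overlap.
#' @return list: `score`, `n_pairs`.
#' @export
inter_domain_score <- function(oe, domain_a, domain_b) {
  stopifnot(is_intra(oe))
  if (max(domain_a$start[1], domain_b$start[1]) <
      min(domain_a$end[1], domain_b$end[1]))
    stop("inter_domain_score: overlapping domains")
  n <- nrow(oe$counts)
  ba <- bins_in_interval(domain_a$start[1], domain_a$end[1], oe$resolution, n)
  bb <- bins_in_interval(domain_b$start[1], domain_b$end[1], oe$resolution, n)
  if (!length(ba) || !length(bb))
    stop("inter_domain_score: a domain spans no full bin")
  vals <- oe$counts[ba, bb]
  vals <- vals[!is.na(vals)]
  if (!length(vals)) stop("inter_domain_score: all entries masked")
  list(score = mean(vals), n_pairs = length(vals))
}

#' Fold changes of inter-domain (domain-pair) interactions
#'
#' For each intrachromosomal pair of non-overlapping domains, scores the
#' cross rectangle in O/E space in both conditions and reports
#' `FC = treated / untreated`.
#'
#' @param treated,untreated intra [contact_matrix()] or named list thereof.
#' @param pairs list of two-element lists/data.frames: each element a
#'   one-row domain (chrom, start, end); both domains of a pair on the same
#'   chromosome.
#' @param labels optional character vector labelling each pair (e.g.
#'   `"DSB-DSB"` / `"Ctrl-Ctrl"`); summaries are grouped by it.
#' @return list: `per_pair` data.frame, `summary` per label, `tests` (named
#'   list of one-tailed paired t of each label's FCs vs 1).
#' @export
inter_domain_pair_fc <- function(treated, untreated, pairs, labels = NULL) {
  treated <- as_matrix_list(treated)
  untreated <- as_matrix_list(untreated)
  oe_t <- lapply(treated, oe_normalize)
  oe_u <- lapply(untreated, oe_normalize)
  if (is.null(labels)) labels <- rep("pair", length(pairs))
  rows <- list()
  for (k in seq_along(pairs)) {
    a <- pairs[[k]][[1]]; b <- pairs[[k]][[2]]
    ch <- a$chrom[1]
    if (b$chrom[1] != ch)
      stop("inter_domain_pair_fc: pair ", k, " is not intrachromosomal")
    st <- inter_domain_score(oe_t[[ch]], a, b)
    su <- inter_domain_score(oe_u[[ch]], a, b)
    rows[[k]] <- data.frame(
      pair = k, label = labels[k], chrom = ch,
      start_a = a$start[1], start_b = b$start[1],
      score_treated = st$score, score_untreated = su$score,
      fc = st$score / su$score, stringsAsFactors = FALSE)
  }
  per_pair <- do.call(rbind, c(rows, make.row.names = FALSE))
  summary <- do.call(rbind, lapply(unique(per_pair$label), function(l) {
    data.frame(label = l, n = sum(per_pair$label == l),
               mean_fc = mean(per_pair$fc[per_pair$label == l]))
  }))
  tests <- list()
  for (l in unique(per_pair$label)) {
    v <- per_pair$fc[per_pair$label == l]
    if (length(v) >= 2 && stats::sd(v) > 0)
      tests[[l]] <- paired_t(v, rep(1, length(v)), tails = "one")
  }
  list(per_pair = per_pair, summary = summary, tests = tests)
}

#' 4C-like viewpoint track
#'
#' Per-bin log2 fold change of raw (non-O/E) normalized contacts of one
#' anchor bin against all bins within a +/- 2 Mb window, pseudocount 1:
#' `log2((treated[anchor, j] + 1) / (untreated[anchor, j] + 1))`.
#'
#' @param treated,untreated intra [contact_matrix()] at equal resolution.
#' @param anchor_bin 0-based bin index of the viewpoint.
#' @param half_window window half-width in bp (default 2 Mb).
#' @param pc pseudocount (default 1).
#' @return data.frame: bin (0-based), start (bp), log2fc.
#' @export
viewpoint_track <- function(treated, untreated, anchor_bin,
                            half_window = 2e6, pc = 1) {
  stopifnot(is_intra(treated), is_intra(untreated),
            treated$resolution == untreated$resolution)
  n <- nrow(treated$counts)
  if (anchor_bin < 0 || anchor_bin >= n)
    stop("viewpoint_track: anchor_bin out of range")
  w <- floor(half_window / treated$resolution)
  j <- max(0, anchor_bin - w):min(n - 1, anchor_bin + w)
  t_row <- treated$counts[anchor_bin + 1, j + 1]
  u_row <- untreated$counts[anchor_bin + 1, j + 1]
  data.frame(bin = j, start = j * treated$resolution,
             log2fc = log2((t_row + pc) / (u_row + pc)))
}

#' Translocation-window contact score
#'
#' Sum of counts over the 5x5-bin block centered on the bin pair containing
#' the two sites (a 1.25 Mb x 1.25 Mb region at 250 kb resolution),
#' edge-clipped at matrix boundaries.
#'
#' @param m a [contact_matrix()] (inter-chromosomal at 250 kb in the
#'   canonical use; other inputs are scored with the same block-in-bins
#'   semantics, with a warning for other resolutions).
#' @param site_a,site_b bp positions on `m$chrom_a` / `m$chrom_b`.
#' @param flank_bins bins on each side of the central bin (default 2).
#' @param warn warn when the resolution is not 250 kb.
#' @return numeric block sum.
#' @export
trans_window_score <- function(m, site_a, site_b, flank_bins = 2,
                               warn = TRUE) {
  if (warn && m$resolution != 2.5e5)
    warning("trans_window_score: resolution is ", m$resolution,
            " bp, not 250 kb; proceeding with the ",
            2 * flank_bins + 1, "-bin block")
  i <- pos_to_bin(site_a, m$resolution) + 1
  j <- pos_to_bin(site_b, m$resolution) + 1
  if (i < 1 || i > nrow(m$counts) || j < 1 || j > ncol(m$counts))
    stop("trans_window_score: site outside matrix")
  ri <- max(1, i - flank_bins):min(nrow(m$counts), i + flank_bins)
  rj <- max(1, j - flank_bins):min(ncol(m$counts), j + flank_bins)
  sum(m$counts[ri, rj], na.rm = TRUE)
}

#' log2 fold change of two window sums
#'
#' `log2((sum_t + pc) / (sum_u + pc))` with pseudocount 0.1 by default.
#'
#' @param sum_t,sum_u non-negative window sums.
#' @param pc pseudocount.
#' @return numeric.
#' @export
trans_window_log2fc <- function(sum_t, sum_u, pc = 0.1) {
  if (any(sum_t < 0) || any(sum_u < 0))
    stop("trans_window_log2fc: negative sum")
  log2((sum_t + pc) / (sum_u + pc))
}
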