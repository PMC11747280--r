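# Independent brute-force oracles used to cross-check the vectorized
# implementations. These deliberately use naive loops.

oracle_expected_profile <- function(counts) {
  n <- nrow(counts)
  sapply(0:(n - 1), function(d) {
    vals <- c()
    for (i in 1:(n - d)) vals <- c(vals, counts[i, i + d])
    mean(vals)
  })
}

oracle_oe <- function(counts) {
  prof <- oracle_expected_profile(counts)
  n <- nrow(counts)
  out <- matrix(NA_real_, n, n)
  for (i in 1:n) for (j in 1:n) {
    e <- prof[abs(i - j) + 1]
    out[i, j] <- if (e == 0) NA_real_ else counts[i, j] / e
  }
  out
}

# mean of oe over bins pairs i<j fully inside [start, end)
oracle_intra_score <- function(oe, start, end, resolution) {
  n <- nrow(oe)
  bins <- c()
  for (b in 0:(n - 1))
    if (b * resolution >= start && (b + 1) * resolution <= end)
      bins <- c(bins, b + 1)
  vals <- c()
  for (a in seq_along(bins)) for (b in seq_along(bins))
    if (a < b) vals <- c(vals, oe[bins[a], bins[b]])
  mean(vals, na.rm = TRUE)
}

oracle_rect_score <- function(oe, sa, ea, sb, eb, resolution) {
  n <- nrow(oe)
  in_dom <- function(s, e) {
    bins <- c()
    for (b in 0:(n - 1))
      if (b * resolution >= s && (b + 1) * resolution <= e)
        bins <- c(bins, b + 1)
    bins
  }
  ba <- in_dom(sa, ea); bb <- in_dom(sb, eb)
  vals <- c()
  for (i in ba) for (j in bb) vals <- c(vals, oe[i, j])
  mean(vals, na.rm = TRUE)
}

oracle_window_sum <- function(counts, i0, j0, flank) {
  total <- 0
  for (i in (i0 - flank):(i0 + flank)) for (j in (j0 - flank):(j0 + flank))
    if (i >= 1 && i <= nrow(counts) && j >= 1 && j <= ncol(counts))
      total <- total + counts[i, j]
  total
}

oracle_mh <- function(bait, prey) {
  best <- 0
  for (k in 1:min(nchar(bait), nchar(prey))) {
    suf <- substr(bait, nchar(bait) - k + 1, nchar(bait))
    pre <- substr(prey, 1, k)
    if (suf == pre && !grepl("N", suf)) best <- k
  }
  best
}

oracle_anchor_calls <- function(rad21, ctcf, gap) {
  keep <- rep(FALSE, nrow(rad21))
  for (i in seq_len(nrow(rad21))) {
    for (j in seq_len(nrow(ctcf))) {
      if (rad21$chrom[i] == ctcf$chrom[j] &&
          abs(rad21$summit[i] - ctcf$summit[j]) <= gap) {
        keep[i] <- TRUE
        break
      }
    }
  }
  rad21[keep, , drop = FALSE]
}

oracle_min_distance <- function(point, sites) {
  best <- Inf
  for (i in seq_len(nrow(sites))) {
    mid <- floor((sites$start[i] + sites$end[i]) / 2)
    d <- if (point >= sites$start[i] && point < sites$end[i]) 0
         else abs(point - mid)
    best <- min(best, d)
  }
  best
}

# naive 8-mer sliding-window motif scan
oracle_asisi_scan <- function(seq) {
  hits <- c()
  if (nchar(seq) < 8) return(hits)
  for (s in 1:(nchar(seq) - 7))
    if (substr(seq, s, s + 7) == "GCGATCGC") hits <- c(hits, s - 1)
  hits
}

random_symmetric_counts <- function(n, lambda = 5) {
  m <- matrix(0, n, n)
  ut <- upper.tri(m, diag = TRUE)
  m[ut] <- rpois(sum(ut), lambda)
  m + t(m) - diag(diag(m), n)
}
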