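# Internal helpers.

# Evaluate expr with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}

# Merge per-chromosome intervals that overlap or touch; df has chrom/start/end.
merge_intervals <- function(df) {
  if (nrow(df) < 2) return(df)
  out <- list()
  for (ch in unique(df$chrom)) {
    sub <- df[df$chrom == ch, , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    s <- sub$start[1]; e <- sub$end[1]
    rows <- list()
    for (i in seq_len(nrow(sub))[-1]) {
      if (sub$start[i] <= e) e <- max(e, sub$end[i])
      else { rows[[length(rows) + 1]] <- c(s, e); s <- sub$start[i]; e <- sub$end[i] }
    }
    rows[[length(rows) + 1]] <- c(s, e)
    m <- do.call(rbind, rows)
    out[[ch]] <- data.frame(chrom = ch, start = m[, 1], end = m[, 2],
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

# Is position pos (same chromosome assumed filtered by caller) inside any
# of the given intervals? Vectorized over pos.
point_in_intervals <- function(chrom, pos, intervals) {
  if (is.null(intervals) || nrow(intervals) == 0)
    return(rep(FALSE, length(pos)))
  vapply(seq_along(pos), function(i) {
    sel <- intervals$chrom == chrom[i]
    any(pos[i] >= intervals$start[sel] & pos[i] < intervals$end[sel])
  }, logical(1))
}
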