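#' Binned coverage track
#'
#' Per-chromosome arrays of non-negative, rpkm-like values on a fixed bin
#' grid. Bin `i` (0-based) covers `[i * bin_size, (i + 1) * bin_size)`;
#' the final bin may be ragged.
#'
#' @param bin_size bin width in bp.
#' @param values named list of numeric vectors, one per chromosome; each of
#'   length `ceiling(chrom_length / bin_size)`.
#' @param layout the [genome_layout()] the track lives on.
#' @return object of class `coverage_track`.
#' @export
coverage_track <- function(bin_size, values, layout) {
  bin_size <- as.numeric(bin_size)
  if (bin_size <= 0) stop("bin_size must be positive")
  if (!all(names(values) %in% layout$chrom_names))
    stop("coverage_track: values named by unknown chromosome")
  for (ch in layout$chrom_names) {
    n <- ceiling(layout$chrom_lengths[[ch]] / bin_size)
    if (is.null(values[[ch]])) values[[ch]] <- numeric(n)
    if (length(values[[ch]]) != n)
      stop("coverage_track: ", ch, " needs ", n, " bins, got ",
           length(values[[ch]]))
    if (any(values[[ch]] < 0))
      stop("coverage_track: negative values on ", ch)
  }
  structure(list(bin_size = bin_size, values = values[layout$chrom_names],
                 layout = layout),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat("coverage_track: bin", x$bin_size, "bp,",
      sum(lengths(x$values)), "bins over",
      length(x$values), "chromosome(s)\n")
  invisible(x)
}

n_bins <- function(layout, chrom, bin_size) {
  ceiling(layout$chrom_lengths[[chrom]] / bin_size)
}

#' Mean per-bp track value over an interval
#'
#' Averages bin values weighted by the number of bp each bin contributes to
#' the interval, so the result is robust to interval/bin misalignment.
#'
#' @param track a [coverage_track()].
#' @param chrom,start,end interval (0-based half-open, vectors allowed).
#' @return numeric vector of per-bp means.
#' @export
interval_mean <- function(track, chrom, start, end) {
  bs <- track$bin_size
  mapply(function(ch, s, e) {
    v <- track$values[[ch]]
    if (is.null(v)) stop("interval_mean: unknown chromosome ", ch)
    e <- min(e, length(v) * bs)
    b0 <- floor(s / bs); b1 <- floor((e - 1) / bs)
    bins <- b0:b1
    lo <- pmax(bins * bs, s)
    hi <- pmin((bins + 1) * bs, e)
    w <- hi - lo
    sum(v[bins + 1] * w) / sum(w)
  }, chrom, start, end, USE.NAMES = FALSE)
}

# Aggregate a track to a coarser grid by averaging whole bins.
aggregate_track <- function(track, factor) {
  stopifnot(factor >= 1)
  vals <- lapply(track$values, function(v) {
    grp <- (seq_along(v) - 1) %/% factor
    as.numeric(tapply(v, grp, mean))
  })
  structure(list(bin_size = track$bin_size * factor, values = vals,
                 layout = track$layout),
            class = "coverage_track")
}
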