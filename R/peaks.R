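#' Signal peak table
#'
#' Peaks carry an interval, a summit position and an rpkm-like signal.
#'
#' @param chrom,start,end interval fields (0-based half-open).
#' @param summit summit position, `start <= summit < end`.
#' @param signal non-negative signal.
#' @param layout optional [genome_layout()] for bounds checking.
#' @return data.frame with columns chrom, start, end, summit, signal.
#' @export
signal_peaks <- function(chrom, start, end, summit, signal, layout = NULL) {
  df <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end), summit = as.numeric(summit),
                   signal = as.numeric(signal), stringsAsFactors = FALSE)
  df$strand <- rep_len(".", nrow(df))
  validate_intervals(df, layout, what = "peak")
  df$strand <- NULL
  if (any(df$summit < df$start | df$summit >= df$end))
    stop("signal_peaks: summit must lie within the peak interval")
  if (any(df$signal < 0)) stop("signal_peaks: signal must be >= 0")
  df
}

#' Damage domain table
#'
#' TAD or gamma-H2AX intervals labelled damaged (containing at least one
#' DSB) or control. Intervals of one kind must be non-overlapping.
#'
#' @param chrom,start,end interval fields.
#' @param kind `"TAD"` or `"GH2AX"` (recycled).
#' @param damaged logical flag (recycled).
#' @param layout optional [genome_layout()].
#' @return data.frame with columns chrom, start, end, kind, damaged.
#' @export
damage_domains <- function(chrom, start, end, kind = "GH2AX",
                           damaged = FALSE, layout = NULL) {
  kind <- rep_len(as.character(kind), length(chrom))
  if (!all(kind %in% c("TAD", "GH2AX")))
    stop("damage_domains: kind must be TAD or GH2AX")
  df <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end), kind = kind,
                   damaged = rep_len(as.logical(damaged), length(chrom)),
                   stringsAsFactors = FALSE)
  df$strand <- rep_len(".", nrow(df))
  validate_intervals(df, layout, what = "domain")
  df$strand <- NULL
  for (k in unique(df$kind)) for (ch in unique(df$chrom)) {
    sub <- df[df$kind == k & df$chrom == ch, , drop = FALSE]
    if (nrow(sub) < 2) next
    sub <- sub[order(sub$start), , drop = FALSE]
    if (any(sub$start[-1] < sub$end[-nrow(sub)]))
      stop("damage_domains: overlapping ", k, " domains on ", ch)
  }
  df
}
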