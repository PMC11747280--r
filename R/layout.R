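#' Genome layout
#'
#' A minimal chromosome model: names, lengths and (optionally) sequence.
#' All coordinates in the package are 0-based, half-open (BED convention).
#'
#' @param chrom_names character vector of unique chromosome names.
#' @param chrom_lengths integer-ish vector of chromosome lengths in bp,
#'   parallel to `chrom_names` (or named by them).
#' @param sequence optional named character vector of uppercase ACGTN
#'   sequences, one per chromosome; lengths must equal `chrom_lengths`.
#' @return an object of class `genome_layout`.
#' @export
genome_layout <- function(chrom_names, chrom_lengths, sequence = NULL) {
  chrom_names <- as.character(chrom_names)
  if (anyDuplicated(chrom_names))
    stop("chromosome names must be unique")
  chrom_lengths <- as.numeric(chrom_lengths)
  if (length(chrom_lengths) != length(chrom_names))
    stop("chrom_lengths must be parallel to chrom_names")
  if (any(!is.finite(chrom_lengths)) || any(chrom_lengths <= 0))
    stop("all chromosome lengths must be positive")
  names(chrom_lengths) <- chrom_names
  if (!is.null(sequence)) {
    sequence <- vapply(sequence, toupper, character(1))
    if (is.null(names(sequence)) || !all(names(sequence) %in% chrom_names))
      stop("sequence must be named by chromosome")
    for (ch in names(sequence)) {
      if (nchar(sequence[[ch]]) != chrom_lengths[[ch]])
        stop("sequence length for ", ch, " does not match chrom_length")
      if (grepl("[^ACGTN]", sequence[[ch]]))
        stop("sequence for ", ch, " contains characters outside ACGTN")
    }
  }
  structure(
    list(chrom_names = chrom_names, chrom_lengths = chrom_lengths,
         sequence = sequence),
    class = "genome_layout"
  )
}

#' @export
print.genome_layout <- function(x, ...) {
  cat("genome_layout:", length(x$chrom_names), "chromosome(s),",
      format(sum(x$chrom_lengths), big.mark = ","), "bp total",
      if (!is.null(x$sequence)) "(with sequence)" else "", "\n")
  invisible(x)
}

#' @export
length.genome_layout <- function(x) length(x$chrom_names)

chrom_length <- function(layout, chrom) {
  if (!chrom %in% layout$chrom_names)
    stop("unknown chromosome: ", chrom)
  layout$chrom_lengths[[chrom]]
}

#' Genomic interval table
#'
#' Builds a validated data.frame of genomic intervals. Coordinates are
#' 0-based half-open; strand is one of `+`, `-`, `.` and is carried but
#' ignored by all distance computations.
#'
#' @param chrom character vector.
#' @param start,end numeric vectors, 0-based half-open (`start < end`).
#' @param strand character vector (recycled), one of `+`, `-`, `.`.
#' @param name,score optional per-interval annotation.
#' @param layout optional [genome_layout()]; if given, intervals are checked
#'   against chromosome bounds.
#' @return data.frame with columns chrom, start, end, strand (+ name, score).
#' @export
genomic_intervals <- function(chrom, start, end, strand = ".",
                              name = NULL, score = NULL, layout = NULL) {
  df <- data.frame(chrom = as.character(chrom),
                   start = as.numeric(start),
                   end = as.numeric(end),
                   strand = rep_len(as.character(strand), length(chrom)),
                   stringsAsFactors = FALSE)
  if (!is.null(name)) df$name <- as.character(name)
  if (!is.null(score)) df$score <- as.numeric(score)
  validate_intervals(df, layout)
  df
}

validate_intervals <- function(df, layout = NULL, what = "interval") {
  if (nrow(df) == 0) return(invisible(df))
  bad <- which(!(df$start >= 0 & df$start < df$end))
  if (length(bad))
    stop(what, " validation error: start must satisfy 0 <= start < end ",
         "(row ", bad[1], ": ", df$chrom[bad[1]], ":", df$start[bad[1]],
         "-", df$end[bad[1]], ")")
  if (!all(df$strand %in% c("+", "-", ".")))
    stop(what, " validation error: strand must be one of +, -, .")
  if (!is.null(layout)) {
    unknown <- setdiff(unique(df$chrom), layout$chrom_names)
    if (length(unknown))
      stop(what, " validation error: unknown chromosome ", unknown[1])
    lens <- layout$chrom_lengths[df$chrom]
    bad <- which(df$end > lens)
    if (length(bad))
      stop(what, " validation error: interval beyond chromosome end (row ",
           bad[1], ")")
  }
  invisible(df)
}

#' DSB site table
#'
#' Cut sites are intervals of width 8 (an AsiSI recognition site) or width 1
#' (an abstract cut). The cut midpoint, used by all distance computations,
#' is `floor((start + end) / 2)`.
#'
#' @param id unique site identifiers.
#' @param chrom,start,end interval fields (0-based half-open).
#' @param is_bait logical flag (recycled).
#' @param layout optional [genome_layout()] for bounds checking.
#' @return data.frame with columns id, chrom, start, end, is_bait.
#' @export
dsb_sites <- function(id, chrom, start, end, is_bait = FALSE, layout = NULL) {
  id <- as.character(id)
  if (anyDuplicated(id)) stop("DSB site ids must be unique")
  df <- data.frame(id = id, chrom = as.character(chrom),
                   start = as.numeric(start), end = as.numeric(end),
                   is_bait = rep_len(as.logical(is_bait), length(id)),
                   stringsAsFactors = FALSE)
  df$strand <- rep_len(".", nrow(df))
  validate_intervals(df, layout, what = "DSB site")
  df$strand <- NULL
  df
}

#' Cut midpoint of DSB sites
#'
#' The reference position used by all distance computations:
#' `floor((start + end) / 2)`.
#'
#' @param dsbs a [dsb_sites()] data.frame.
#' @return numeric vector of midpoints (bp).
#' @export
cut_midpoint <- function(dsbs) floor((dsbs$start + dsbs$end) / 2)

#' Minimum distance from a point to a set of cut sites
#'
#' Distance is measured to each site's cut midpoint; a point lying inside a
#' cut interval has distance 0. The caller is responsible for restricting
#' `sites` to the relevant chromosome.
#'
#' @param point position in bp (0-based).
#' @param sites data.frame as returned by [dsb_sites()].
#' @return minimum distance in bp.
#' @export
min_distance <- function(point, sites) {
  if (is.null(sites) || nrow(sites) == 0)
    stop("min_distance: empty site list")
  mids <- cut_midpoint(sites)
  d <- abs(point - mids)
  inside <- point >= sites$start & point < sites$end
  d[inside] <- 0
  min(d)
}

#' Scan a genome for AsiSI recognition sites
#'
#' Finds all occurrences of the 8-bp AsiSI site `GCGATCGC`. The motif is its
#' own reverse complement, so a single forward scan reports every cuttable
#' position exactly once. `N` bases never match.
#'
#' @param layout a [genome_layout()] carrying sequence.
#' @return a [dsb_sites()] data.frame (width-8 intervals), sorted by
#'   chromosome then start; empty if the motif is absent.
#' @export
find_asisi_sites <- function(layout) {
  if (is.null(layout$sequence))
    stop("find_asisi_sites: layout carries no sequence")
  motif <- "GCGATCGC"
  out <- list()
  for (ch in layout$chrom_names) {
    seq <- layout$sequence[[ch]]
    if (is.null(seq)) next
    m <- Biostrings::matchPattern(motif, Biostrings::DNAString(seq),
                                  fixed = TRUE)
    if (length(m) == 0) next
    starts <- Biostrings::start(m) - 1L  # to 0-based
    out[[ch]] <- data.frame(chrom = ch, start = as.numeric(starts),
                            stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(dsb_sites(character(0), character(0), numeric(0), numeric(0)))
  df <- do.call(rbind, out)
  ord <- order(match(df$chrom, layout$chrom_names), df$start)
  df <- df[ord, , drop = FALSE]
  dsb_sites(id = sprintf("asisi_%s_%d", df$chrom, df$start),
            chrom = df$chrom, start = df$start, end = df$start + 8,
            layout = layout)
}

#' rpkm normalization
#'
#' Reads per kilobase of window per million mapped reads.
#'
#' @param read_count number of reads in the window (>= 0).
#' @param window_bp window size in bp (> 0).
#' @param library_size total mapped reads (> 0).
#' @return rpkm value.
#' @export
rpkm_normalize <- function(read_count, window_bp, library_size) {
  if (any(window_bp <= 0)) stop("rpkm_normalize: window_bp must be > 0")
  if (any(library_size <= 0)) stop("rpkm_normalize: library_size must be > 0")
  if (any(read_count < 0)) stop("rpkm_normalize: read_count must be >= 0")
  read_count / ((window_bp / 1000) * (library_size / 1e6))
}
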