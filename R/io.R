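#' Read a BED3/BED6 file
#'
#' Tab-separated, 0-based half-open. Name, score and strand columns are
#' preserved when present.
#'
#' @param path file path.
#' @param layout optional [genome_layout()] for bounds checking.
#' @return interval data.frame in file order (see [genomic_intervals()]).
#' @export
read_bed <- function(path, layout = NULL) {
  if (!file.exists(path)) stop("read_bed: file not found: ", path)
  df <- tryCatch(
    utils::read.table(path, sep = "\t", header = FALSE,
                      colClasses = "character", quote = "",
                      comment.char = "#"),
    error = function(e) stop("read_bed: parse error in ", path, ": ",
                             conditionMessage(e)))
  if (ncol(df) < 3)
    stop("read_bed: need at least 3 columns, got ", ncol(df))
  out <- data.frame(chrom = df[[1]],
                    start = suppressWarnings(as.numeric(df[[2]])),
                    end = suppressWarnings(as.numeric(df[[3]])),
                    strand = ".", stringsAsFactors = FALSE)
  bad <- which(is.na(out$start) | is.na(out$end))
  if (length(bad))
    stop("read_bed: parse error at line ", bad[1], ": non-numeric coordinate")
  if (ncol(df) >= 4) out$name <- df[[4]]
  if (ncol(df) >= 5) out$score <- suppressWarnings(as.numeric(df[[5]]))
  if (ncol(df) >= 6) out$strand <- df[[6]]
  validate_intervals(out, layout, what = "BED")
  out
}

#' Write intervals as BED
#'
#' Writes BED6 when name/score/strand are informative, else BED3.
#'
#' @param intervals interval data.frame.
#' @param path output path.
#' @export
write_bed <- function(intervals, path) {
  cols <- data.frame(chrom = intervals$chrom,
                     start = format(intervals$start, scientific = FALSE,
                                    trim = TRUE),
                     end = format(intervals$end, scientific = FALSE,
                                  trim = TRUE))
  has6 <- !is.null(intervals$name) || !is.null(intervals$score) ||
    any(intervals$strand != ".")
  if (has6) {
    cols$name <- if (is.null(intervals$name)) "." else intervals$name
    cols$score <- if (is.null(intervals$score)) 0 else intervals$score
    cols$strand <- if (is.null(intervals$strand)) "." else intervals$strand
  }
  data.table::fwrite(cols, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a grid-aligned bedGraph into a coverage track
#'
#' Every record must start on the stated bin grid and span exactly one bin
#' (the final, possibly ragged bin may end at the chromosome end). Unlisted
#' bins are zero.
#'
#' @param path file path.
#' @param bin_size expected bin width in bp.
#' @param layout [genome_layout()].
#' @return a [coverage_track()].
#' @export
read_bedgraph <- function(path, bin_size, layout) {
  if (!file.exists(path)) stop("read_bedgraph: file not found: ", path)
  vals <- lapply(layout$chrom_names,
                 function(ch) numeric(n_bins(layout, ch, bin_size)))
  names(vals) <- layout$chrom_names
  if (file.size(path) > 0) {
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            colClasses = c("character", "numeric",
                                           "numeric", "numeric"))
    unknown <- setdiff(unique(df[[1]]), layout$chrom_names)
    if (length(unknown))
      stop("read_bedgraph: unknown chromosome ", unknown[1])
    lens <- layout$chrom_lengths[df[[1]]]
    ok_grid <- df[[2]] %% bin_size == 0 &
      (df[[3]] == df[[2]] + bin_size | df[[3]] == lens)
    if (!all(ok_grid))
      stop("read_bedgraph: record at line ", which(!ok_grid)[1],
           " is not aligned to the ", bin_size, " bp grid")
    if (any(df[[3]] > lens))
      stop("read_bedgraph: record beyond chromosome end at line ",
           which(df[[3]] > lens)[1])
    for (ch in unique(df[[1]])) {
      sel <- df[[1]] == ch
      vals[[ch]][df[[2]][sel] / bin_size + 1] <- df[[4]][sel]
    }
  }
  coverage_track(bin_size, vals, layout)
}

#' Write a coverage track as bedGraph
#'
#' Zero bins are omitted (canonical sparse form).
#'
#' @param track a [coverage_track()].
#' @param path output path.
#' @param digits significant digits for values.
#' @export
write_bedgraph <- function(track, path, digits = 6) {
  bs <- track$bin_size
  rows <- lapply(names(track$values), function(ch) {
    v <- track$values[[ch]]
    nz <- which(v != 0)
    if (!length(nz)) return(NULL)
    len <- track$layout$chrom_lengths[[ch]]
    data.frame(chrom = ch, start = (nz - 1) * bs,
               end = pmin(nz * bs, len),
               value = signif(v[nz], digits), stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) df <- data.frame(chrom = character(0), start = numeric(0),
                                    end = numeric(0), value = numeric(0))
  df$start <- format(df$start, scientific = FALSE, trim = TRUE)
  df$end <- format(df$end, scientific = FALSE, trim = TRUE)
  data.table::fwrite(df, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read contact matrices from dump-style triplets
#'
#' Format: a single header line `#resolution=<bp>` followed by tab-separated
#' records `chromA startA chromB startB count`, starts aligned to the
#' resolution grid. Intra-chromosomal records are symmetrized (the count is
#' assigned to both (i, j) and (j, i)); unlisted pairs are zero.
#'
#' @param path file path.
#' @param layout [genome_layout()].
#' @param resolution optional; must agree with the file header when given.
#' @return named list of [contact_matrix()], keyed `"chromA|chromB"`.
#' @export
read_contacts <- function(path, layout, resolution = NULL) {
  if (!file.exists(path)) stop("read_contacts: file not found: ", path)
  header <- readLines(path, n = 1)
  if (!grepl("^#resolution=\\d+$", header))
    stop("read_contacts: missing '#resolution=<bp>' header")
  res <- as.numeric(sub("^#resolution=", "", header))
  if (!is.null(resolution) && resolution != res)
    stop("read_contacts: header resolution ", res,
         " does not match requested ", resolution)
  df <- utils::read.table(path, sep = "\t", header = FALSE, skip = 1,
                          colClasses = c("character", "numeric", "character",
                                         "numeric", "numeric"))
  if (any(df[[5]] < 0))
    stop("read_contacts: negative count at line ",
         which(df[[5]] < 0)[1] + 1)
  off <- which(df[[2]] %% res != 0 | df[[4]] %% res != 0)
  if (length(off))
    stop("read_contacts: start not aligned to ", res, " bp grid at line ",
         off[1] + 1)
  unknown <- setdiff(unique(c(df[[1]], df[[3]])), layout$chrom_names)
  if (length(unknown))
    stop("read_contacts: unknown chromosome ", unknown[1])
  keys <- paste(df[[1]], df[[3]], sep = "|")
  out <- list()
  for (key in unique(keys)) {
    sel <- keys == key
    ca <- df[[1]][sel][1]; cb <- df[[3]][sel][1]
    na <- n_bins(layout, ca, res); nb_ <- n_bins(layout, cb, res)
    m <- matrix(0, na, nb_)
    i <- df[[2]][sel] / res + 1
    j <- df[[4]][sel] / res + 1
    if (any(i > na) || any(j > nb_))
      stop("read_contacts: bin beyond chromosome end for ", key)
    m[cbind(i, j)] <- df[[5]][sel]
    if (ca == cb) {
      lower <- t(m)
      keep <- m == 0 & lower != 0
      m[keep] <- lower[keep]
    }
    out[[key]] <- contact_matrix(ca, cb, res, m, layout)
  }
  out
}

#' Write contact matrices as dump-style triplets
#'
#' Canonical form: one `#resolution=` header, intra-chromosomal matrices as
#' their upper triangle (including the diagonal), all records sorted, zero
#' entries omitted.
#'
#' @param matrices a [contact_matrix()] or list thereof (equal resolutions).
#' @param path output path.
#' @export
write_contacts <- function(matrices, path) {
  if (inherits(matrices, "contact_matrix")) matrices <- list(matrices)
  res <- unique(vapply(matrices, function(m) m$resolution, numeric(1)))
  if (length(res) != 1)
    stop("write_contacts: matrices must share one resolution")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#resolution=%d", as.integer(res)), con)
  for (m in matrices) {
    cm <- m$counts
    idx <- which(cm != 0, arr.ind = TRUE)
    if (is_intra(m)) idx <- idx[idx[, 1] <= idx[, 2], , drop = FALSE]
    if (nrow(idx)) {
      idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
      df <- data.frame(a = m$chrom_a,
                       sa = format((idx[, 1] - 1) * res,
                                   scientific = FALSE, trim = TRUE),
                       b = m$chrom_b,
                       sb = format((idx[, 2] - 1) * res,
                                   scientific = FALSE, trim = TRUE),
                       n = cm[idx])
      utils::write.table(df, con, sep = "\t", col.names = FALSE,
                         row.names = FALSE, quote = FALSE)
    }
  }
  invisible(path)
}

junction_columns <- c("read_id", "bait_chrom", "bait_pos", "bait_strand",
                      "prey_chrom", "prey_pos", "prey_strand",
                      "bait_flank", "prey_flank")

#' Read an HTGTS junction table
#'
#' Tab-separated with the header
#' `read_id bait_chrom bait_pos bait_strand prey_chrom prey_pos prey_strand
#' bait_flank prey_flank`. Flanks are uppercase DNA over ACGTN; `bait_flank`
#' ends at the junction and `prey_flank` starts at it.
#'
#' @param path file path.
#' @return junction data.frame.
#' @export
read_junctions <- function(path) {
  if (!file.exists(path)) stop("read_junctions: file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character", quote = "")
  missing <- setdiff(junction_columns, names(df))
  if (length(missing))
    stop("read_junctions: schema error, missing column(s): ",
         paste(missing, collapse = ", "))
  df <- df[junction_columns]
  df$bait_pos <- as.numeric(df$bait_pos)
  df$prey_pos <- as.numeric(df$prey_pos)
  validate_junctions(df)
  df
}

validate_junctions <- function(df) {
  if (nrow(df) == 0) return(invisible(df))
  if (!all(df$bait_strand %in% c("+", "-")) ||
      !all(df$prey_strand %in% c("+", "-")))
    stop("junction validation error: strand must be + or -")
  if (any(is.na(df$bait_pos)) || any(is.na(df$prey_pos)) ||
      any(df$bait_pos < 0) || any(df$prey_pos < 0))
    stop("junction validation error: positions must be non-negative numbers")
  flanks <- c(df$bait_flank, df$prey_flank)
  if (any(flanks == "") || any(grepl("[^ACGTN]", flanks)))
    stop("junction validation error: flanks must be non-empty ACGTN strings")
  invisible(df)
}

#' Write an HTGTS junction table
#'
#' @param records junction data.frame (see [read_junctions()] for schema).
#' @param path output path.
#' @export
write_junctions <- function(records, path) {
  df <- records[junction_columns]
  df$bait_pos <- format(df$bait_pos, scientific = FALSE, trim = TRUE)
  df$prey_pos <- format(df$prey_pos, scientific = FALSE, trim = TRUE)
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read genome sequence from FASTA into a layout
#'
#' @param path FASTA path.
#' @return a [genome_layout()] with sequence attached.
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- as.character(ss)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  genome_layout(names(seqs), nchar(seqs), sequence = seqs)
}

#' Write a layout's sequence as FASTA
#'
#' @param layout a [genome_layout()] with sequence.
#' @param path output path.
#' @export
write_genome_fasta <- function(layout, path) {
  if (is.null(layout$sequence)) stop("layout carries no sequence")
  ss <- Biostrings::DNAStringSet(layout$sequence)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
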