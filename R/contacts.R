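#' Binned contact matrix
#'
#' A raw or normalized ligation-frequency matrix for one chromosome (pair).
#' Bin `i` (0-based) covers `[i * resolution, (i + 1) * resolution)`; the
#' final bin is ragged when the resolution does not divide the chromosome
#' length. Intra-chromosomal matrices are symmetric.
#'
#' @param chrom_a,chrom_b chromosome names (equal for intra matrices).
#' @param resolution bin size in bp.
#' @param counts numeric matrix of non-negative values, rows indexed by
#'   `chrom_a` bins and columns by `chrom_b` bins.
#' @param layout optional [genome_layout()] used to check dimensions.
#' @return object of class `contact_matrix`.
#' @export
contact_matrix <- function(chrom_a, chrom_b, resolution, counts,
                           layout = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0, na.rm = TRUE))
    stop("contact_matrix: negative counts")
  if (!is.null(layout)) {
    na <- n_bins(layout, chrom_a, resolution)
    nb <- n_bins(layout, chrom_b, resolution)
    if (nrow(counts) != na || ncol(counts) != nb)
      stop("contact_matrix: dimensions ", nrow(counts), "x", ncol(counts),
           " inconsistent with layout (", na, "x", nb, ")")
  }
  if (identical(chrom_a, chrom_b)) {
    if (nrow(counts) != ncol(counts))
      stop("contact_matrix: intra-chromosomal matrix must be square")
    if (any(abs(counts - t(counts)) > 1e-8, na.rm = TRUE))
      stop("contact_matrix: intra-chromosomal matrix must be symmetric")
  }
  structure(list(chrom_a = chrom_a, chrom_b = chrom_b,
                 resolution = as.numeric(resolution), counts = counts),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat("contact_matrix: ", x$chrom_a,
      if (identical(x$chrom_a, x$chrom_b)) "" else paste0(" x ", x$chrom_b),
      " @ ", x$resolution, " bp (", nrow(x$counts), "x", ncol(x$counts),
      "), total ", format(round(sum(x$counts, na.rm = TRUE), 1)), "\n",
      sep = "")
  invisible(x)
}

is_intra <- function(m) identical(m$chrom_a, m$chrom_b)

#' @export
dim.contact_matrix <- function(x) dim(x$counts)

# 0-based bin index of a bp position at the matrix resolution.
pos_to_bin <- function(pos, resolution) floor(pos / resolution)
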