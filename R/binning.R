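#' Partition a multi-chromosome genome into fixed-size bins
#'
#' Builds the coordinate authority used by every contact matrix in the
#' package: an ordered tiling of each chromosome into `bin_size` windows,
#' 0-based and half-open (BED convention). Bin indices are genome-wide,
#' concatenating chromosomes in the order given.
#'
#' @param chrom_sizes Either a named numeric vector of chromosome lengths in
#'   base pairs, or a two-column data.frame `(name, length)`.
#' @param bin_size Bin width in base pairs.
#' @return An object of class `GenomeBinning`: a list with
#'   `chromosomes` (data.frame `name`, `length`), `bin_size`, and `bins`
#'   (data.frame `chrom`, `start`, `end`), plus the per-bin chromosome index
#'   `bin_chrom` and the total bin count `n_bins`.
#' @examples
#' gb <- genome_binning(c(chr1 = 5e6, chr2 = 3e6), bin_size = 1e6)
#' gb$n_bins
#' @export
genome_binning <- function(chrom_sizes, bin_size) {
  if (is.data.frame(chrom_sizes)) {
    nm <- as.character(chrom_sizes[[1]])
    len <- as.numeric(chrom_sizes[[2]])
  } else {
    nm <- names(chrom_sizes)
    len <- as.numeric(chrom_sizes)
  }
  if (is.null(nm) || anyNA(nm) || any(nm == "")) {
    stop("chromosome names are required")
  }
  if (anyDuplicated(nm)) stop("duplicate chromosome names")
  if (any(!is.finite(len)) || any(len <= 0)) stop("chromosome lengths must be positive")
  bin_size <- as.numeric(bin_size)
  if (!is.finite(bin_size) || bin_size <= 0) stop("bin_size must be positive")

  starts <- lapply(len, function(L) (seq_len(ceiling(L / bin_size)) - 1) * bin_size)
  bins <- data.frame(
    chrom = rep(nm, lengths(starts)),
    start = unlist(starts, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  bins$end <- pmin(bins$start + bin_size, rep(len, lengths(starts)))

  obj <- list(
    chromosomes = data.frame(name = nm, length = len, stringsAsFactors = FALSE),
    bin_size = bin_size,
    bins = bins,
    bin_chrom = match(bins$chrom, nm),
    n_bins = nrow(bins)
  )
  class(obj) <- "GenomeBinning"
  obj
}

#' Read a two-column chromosome-sizes file
#'
#' @param path Path to a TSV with columns chromosome name and length (the
#'   standard `chrom.sizes` layout, no header).
#' @return Named numeric vector of lengths.
#' @export
read_chrom_sizes <- function(path) {
  if (!file.exists(path)) stop("chrom sizes file not found: ", path)
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          col.names = c("name", "length"),
                          colClasses = c("character", "numeric"))
  stats::setNames(df$length, df$name)
}

#' @export
print.GenomeBinning <- function(x, ...) {
  cat(sprintf("GenomeBinning: %d chromosomes, %d bins of %s bp\n",
              nrow(x$chromosomes), x$n_bins, format(x$bin_size, big.mark = ",")))
  invisible(x)
}

#' Indices of the bins belonging to one chromosome
#' @param binning A `GenomeBinning`.
#' @param chrom Chromosome name or index.
#' @return Integer vector of genome-wide bin indices (1-based, in order).
#' @export
chrom_bins <- function(binning, chrom) {
  ci <- if (is.numeric(chrom)) as.integer(chrom) else match(chrom, binning$chromosomes$name)
  if (is.na(ci) || ci < 1L || ci > nrow(binning$chromosomes)) {
    stop("unknown chromosome: ", chrom)
  }
  which(binning$bin_chrom == ci)
}

same_binning <- function(a, b) {
  isTRUE(all.equal(a$bin_size, b$bin_size)) &&
    identical(a$chromosomes$name, b$chromosomes$name) &&
    isTRUE(all.equal(a$chromosomes$length, b$chromosomes$length))
}

stopifnot_same_binning <- function(a, b) {
  if (!same_binning(a, b)) stop("contact maps do not share a binning")
}

#' Write the bin table as BED3
#' @param binning A `GenomeBinning`.
#' @param path Output path.
#' @export
write_bins_bed <- function(binning, path) {
  df <- binning$bins
  utils::write.table(
    data.frame(df$chrom, format(df$start, scientific = FALSE, trim = TRUE),
               format(df$end, scientific = FALSE, trim = TRUE)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}
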