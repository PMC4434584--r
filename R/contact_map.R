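#' Construct a binned contact map
#'
#' A `ContactMap` holds a symmetric nonnegative matrix of contact values over
#' the bins of a [genome_binning()], together with the raw read counts that
#' support those values. For raw maps the two are the same matrix; after
#' [iterative_correction()] or [apply_compression()] the `counts` slot carries
#' corrected values while `raw` keeps the original read support, which the
#' error model and the mappability rule always operate on.
#'
#' @param binning A `GenomeBinning`.
#' @param counts Symmetric nonnegative numeric matrix, one row/column per bin.
#' @param value_kind `"raw"` or `"corrected"`.
#' @param raw Raw read-count matrix backing `counts`; defaults to `counts`
#'   itself when `value_kind == "raw"`.
#' @param masked Logical per-bin exclusion flags (TRUE = masked out).
#' @return An object of class `ContactMap` with fields `binning`, `counts`,
#'   `raw`, `total` (sum of the matrix: diagonal once, off-diagonals twice),
#'   `value_kind`, `masked`.
#' @export
contact_map <- function(binning, counts, value_kind = c("raw", "corrected"),
                        raw = NULL, masked = NULL) {
  value_kind <- match.arg(value_kind)
  if (!inherits(binning, "GenomeBinning")) stop("binning must be a GenomeBinning")
  counts <- as.matrix(counts)
  n <- binning$n_bins
  if (!all(dim(counts) == c(n, n))) {
    stop(sprintf("counts must be %d x %d to match the binning", n, n))
  }
  if (any(counts < 0)) stop("negative contact values")
  if (max(abs(counts - t(counts))) > 1e-8 * max(1, max(abs(counts)))) {
    stop("counts matrix is not symmetric")
  }
  if (is.null(raw)) {
    if (value_kind == "corrected") stop("corrected maps require the raw support matrix")
    raw <- counts
  }
  if (is.null(masked)) masked <- rep(FALSE, n)
  obj <- list(
    binning = binning,
    counts = counts,
    raw = raw,
    total = sum(counts),
    value_kind = value_kind,
    masked = as.logical(masked)
  )
  class(obj) <- "ContactMap"
  obj
}

#' @export
print.ContactMap <- function(x, ...) {
  cat(sprintf("ContactMap (%s): %d bins, total %.6g, %d masked bins\n",
              x$value_kind, x$binning$n_bins, x$total, sum(x$masked)))
  invisible(x)
}

#' Read a contact map from disk
#'
#' Reads a sparse triplet file (`bin_i`, `bin_j`, `count`, tab-separated with
#' a header, bin indices 0-based and genome-wide) or a dense whitespace
#' matrix, against a chromosome-sizes file and bin size. Triplets given for
#' one triangle are mirrored; the same unordered pair appearing twice is an
#' error.
#'
#' @param matrix_path Path to the matrix file.
#' @param chrom_sizes_path Path to a two-column chrom.sizes TSV.
#' @param bin_size Bin width in base pairs.
#' @param format `"auto"` (sniff by column count), `"triplet"` or `"dense"`.
#' @return A raw `ContactMap`.
#' @export
read_contact_map <- function(matrix_path, chrom_sizes_path, bin_size,
                             format = c("auto", "triplet", "dense")) {
  format <- match.arg(format)
  if (!file.exists(matrix_path)) stop("matrix file not found: ", matrix_path)
  binning <- genome_binning(read_chrom_sizes(chrom_sizes_path), bin_size)
  n <- binning$n_bins

  lines <- readLines(matrix_path)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (format == "auto") {
    probe <- if (length(lines) >= 2) lines[2] else if (length(lines)) lines[1] else ""
    nf <- length(strsplit(trimws(probe), "\\s+")[[1]])
    format <- if (nf == 0 || nf == 3) "triplet" else "dense"
  }

  if (format == "dense") {
    mat <- as.matrix(utils::read.table(matrix_path, header = FALSE))
    dimnames(mat) <- NULL
    if (!all(dim(mat) == c(n, n))) {
      stop(sprintf("dense matrix is %dx%d but the binning has %d bins",
                   nrow(mat), ncol(mat), n))
    }
    return(contact_map(binning, mat))
  }

  counts <- matrix(0, n, n)
  if (length(lines)) {
    header <- grepl("^[^0-9]", trimws(lines[1]))
    body <- if (header) lines[-1] else lines
    line_no <- if (header) seq_along(body) + 1L else seq_along(body)
    if (length(body)) {
      fields <- strsplit(trimws(body), "\\s+")
      bad <- which(lengths(fields) != 3L)
      if (length(bad)) {
        stop(sprintf("malformed triplet at line %d of %s", line_no[bad[1]], matrix_path))
      }
      fm <- matrix(suppressWarnings(as.numeric(unlist(fields))),
                   ncol = 3, byrow = TRUE)
      bad <- which(apply(is.na(fm), 1, any))
      if (length(bad)) {
        stop(sprintf("malformed triplet at line %d of %s", line_no[bad[1]], matrix_path))
      }
      i <- fm[, 1]; j <- fm[, 2]; v <- fm[, 3]
      bad <- which(i < 0 | j < 0 | i >= n | j >= n | i != floor(i) | j != floor(j))
      if (length(bad)) {
        stop(sprintf("bin index out of range at line %d (genome has %d bins)",
                     line_no[bad[1]], n))
      }
      bad <- which(v < 0)
      if (length(bad)) stop(sprintf("negative count at line %d", line_no[bad[1]]))
      key <- pmin(i, j) * n + pmax(i, j)
      bad <- which(duplicated(key))
      if (length(bad)) {
        stop(sprintf("duplicate record for bin pair (%d, %d) at line %d",
                     i[bad[1]], j[bad[1]], line_no[bad[1]]))
      }
      counts[cbind(i, j) + 1L] <- v
      counts[cbind(j, i) + 1L] <- v
    }
  }
  contact_map(binning, counts)
}

#' Write a contact map as sparse upper-triangle triplets
#'
#' The canonical on-disk form: one record per unordered pair with a nonzero
#' value, `bin_i <= bin_j`, 0-based genome-wide indices, full `%.17g`
#' precision so that a read/write round trip is bit exact.
#'
#' @param map A `ContactMap`.
#' @param path Output path.
#' @export
write_contact_map <- function(map, path) {
  ut <- which(upper.tri(map$counts, diag = TRUE) & map$counts != 0, arr.ind = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("bin_i\tbin_j\tcount", con)
  if (nrow(ut)) {
    ord <- order(ut[, 1], ut[, 2])
    ut <- ut[ord, , drop = FALSE]
    writeLines(sprintf("%d\t%d\t%.17g", ut[, 1] - 1L, ut[, 2] - 1L,
                       map$counts[ut]), con)
  }
  invisible(path)
}

#' Relative error of a contact from its read support
#'
#' The shot-noise error model: a contact supported by `K` reads carries a
#' relative error of `sqrt(K) / K` (i.e. `1/sqrt(K)`). Always evaluated on
#' raw read counts, never on corrected values.
#'
#' @param K Read count(s), positive.
#' @return `sqrt(K)/K`, vectorized.
#' @examples
#' interaction_error(4)   # 0.5
#' interaction_error(100) # 0.1
#' @export
interaction_error <- function(K) {
  if (any(!is.finite(K)) || any(K <= 0)) {
    stop("interaction error is undefined for K <= 0")
  }
  sqrt(K) / K
}

#' Mappable contacts of a raw map
#'
#' A bin pair is mappable when it is supported by more than one read.
#' Symmetric pairs are reported once with `i <= j` (0-based indices).
#'
#' @param map A `ContactMap`; the rule is applied to its raw counts.
#' @return Data frame with columns `i`, `j` (0-based) and `count`.
#' @export
mappable_contacts <- function(map) {
  idx <- which(upper.tri(map$raw, diag = TRUE) & map$raw >= 2, arr.ind = TRUE)
  out <- data.frame(i = idx[, 1] - 1L, j = idx[, 2] - 1L, count = map$raw[idx])
  out[order(out$i, out$j), , drop = FALSE]
}

# logical matrix selecting intrachromosomal (cis) entries
cis_mask <- function(binning) {
  outer(binning$bin_chrom, binning$bin_chrom, "==")
}
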