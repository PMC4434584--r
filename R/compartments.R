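#' First-eigenvector (E1) compartment track of a corrected map
#'
#' For each chromosome, the cis block of the corrected matrix is converted to
#' an observed/expected matrix (expected = mean contact value at each
#' separation), then to its Pearson correlation matrix; the leading
#' eigenvector of that matrix is the E1 track. Positive and negative E1
#' values correspond to the A and B compartments: like-sign bins contact
#' each other preferentially, producing the plaid pattern of the map.
#'
#' Eigenvector sign is arbitrary; if `reference` is given (e.g. generator
#' compartment truth, or a GC-content track on real data), each chromosome's
#' track is flipped so it correlates positively with the reference.
#' Otherwise a deterministic skewness rule fixes the sign. The full track is
#' scaled to unit variance over non-missing bins.
#'
#' @param corrected A `CorrectedMap`.
#' @param reference Optional per-bin numeric reference used to orient signs.
#' @param min_bins Minimum unmasked bins a chromosome needs (default 4);
#'   chromosomes below this, or with a degenerate (constant) correlation
#'   matrix, get a missing track with a warning.
#' @return An object of class `EigenTrack`: list with `values` (per-bin E1,
#'   NA where masked or degenerate) and `binning`.
#' @export
compute_e1 <- function(corrected, reference = NULL, min_bins = 4) {
  binning <- corrected$binning
  values <- rep(NA_real_, binning$n_bins)
  for (ci in seq_len(nrow(binning$chromosomes))) {
    idx <- chrom_bins(binning, ci)
    um <- !corrected$masked[idx]
    keep <- idx[um]
    if (length(keep) < min_bins) {
      warning(sprintf("chromosome %s: fewer than %d unmasked bins, E1 set missing",
                      binning$chromosomes$name[ci], min_bins))
      next
    }
    A <- corrected$counts[keep, keep, drop = FALSE]
    OE <- observed_over_expected(A, pos = keep)
    C <- suppressWarnings(stats::cor(OE))
    C[!is.finite(C)] <- 0
    off <- C[upper.tri(C)]
    if (length(off) == 0 || max(off) - min(off) < 1e-12) {
      warning(sprintf("chromosome %s: degenerate correlation matrix, E1 set missing",
                      binning$chromosomes$name[ci]))
      next
    }
    v <- eigen(C, symmetric = TRUE)$vectors[, 1]
    sv <- stats::sd(v)
    if (sv == 0) {
      warning(sprintf("chromosome %s: constant eigenvector, E1 set missing",
                      binning$chromosomes$name[ci]))
      next
    }
    v <- v / sv
    flip <- if (!is.null(reference)) {
      r <- suppressWarnings(stats::cor(v, reference[keep]))
      is.finite(r) && r < 0
    } else {
      s <- sum(v^3)
      if (s != 0) s < 0 else v[1] < 0
    }
    if (flip) v <- -v
    values[keep] <- v
  }
  ok <- is.finite(values)
  if (any(ok)) values[ok] <- values[ok] / stats::sd(values[ok])
  structure(list(values = values, binning = binning), class = "EigenTrack")
}

# observed/expected with expected = mean at each separation; `pos` gives the
# genomic bin positions of the rows so gaps from masking keep true distances
observed_over_expected <- function(A, pos = seq_len(nrow(A))) {
  d <- abs(outer(pos, pos, "-"))
  means <- tapply(A, d, mean)
  expd <- matrix(means[as.character(d)], nrow(A), ncol(A))
  OE <- ifelse(expd > 0, A / expd, 0)
  OE
}

#' Compare two E1 tracks via distance to the regression line
#'
#' Plots the two tracks against each other bin by bin, fits a least-squares
#' line through the dots, and reports each bin's perpendicular distance to
#' that line as the eigenvector difference measure, together with Pearson
#' and Spearman correlations of the tracks. `line = "ols"` (default) fits
#' ordinary least squares of `track_b` on `track_a`; `line = "tls"` fits the
#' total-least-squares (orthogonal) line, which is exactly symmetric under
#' exchanging the tracks.
#'
#' @param track_a,track_b `EigenTrack`s on the same binning.
#' @param line `"ols"` or `"tls"`.
#' @return List with `distance` (per-bin, NA where either track is missing),
#'   `pearson`, `spearman`, `intercept`, `slope`, `n`.
#' @export
compare_e1 <- function(track_a, track_b, line = c("ols", "tls")) {
  line <- match.arg(line)
  stopifnot_same_binning(track_a$binning, track_b$binning)
  x <- track_a$values
  y <- track_b$values
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3) stop("fewer than 3 bins present in both tracks")
  xs <- x[ok]; ys <- y[ok]
  distance <- rep(NA_real_, length(x))

  if (line == "ols") {
    vx <- stats::var(xs)
    if (vx == 0) stop("track_a is constant over the shared bins")
    slope <- stats::cov(xs, ys) / vx
    intercept <- mean(ys) - slope * mean(xs)
    distance[ok] <- abs(ys - (intercept + slope * xs)) / sqrt(1 + slope^2)
  } else {
    cx <- xs - mean(xs); cy <- ys - mean(ys)
    S <- crossprod(cbind(cx, cy)) / (length(cx) - 1)
    u <- eigen(S, symmetric = TRUE)$vectors[, 1]
    distance[ok] <- abs(cx * (-u[2]) + cy * u[1])
    slope <- if (abs(u[1]) > 1e-15) u[2] / u[1] else Inf
    intercept <- mean(ys) - slope * mean(xs)
  }

  pe <- suppressWarnings(stats::cor(xs, ys))
  sp <- suppressWarnings(stats::cor(xs, ys, method = "spearman"))
  list(distance = distance, pearson = pe, spearman = sp,
       intercept = intercept, slope = slope, n = sum(ok))
}

#' Write an E1 track as bedGraph
#' @param track An `EigenTrack`.
#' @param path Output path.
#' @export
write_bedgraph <- function(track, path) {
  df <- track$binning$bins
  ok <- is.finite(track$values)
  utils::write.table(
    data.frame(df$chrom[ok],
               format(df$start[ok], scientific = FALSE, trim = TRUE),
               format(df$end[ok], scientific = FALSE, trim = TRUE),
               sprintf("%.17g", track$values[ok])),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' Read a bedGraph written by [write_bedgraph()] back into an E1 track
#' @param path bedGraph path.
#' @param binning The `GenomeBinning` the track lives on.
#' @return An `EigenTrack` (missing bins NA).
#' @export
read_bedgraph <- function(path, binning) {
  values <- rep(NA_real_, binning$n_bins)
  if (file.size(path) > 0) {
    df <- utils::read.table(path, header = FALSE, sep = "\t",
                            col.names = c("chrom", "start", "end", "value"),
                            colClasses = c("character", "numeric", "numeric",
                                           "numeric"))
    key_bin <- paste(binning$bins$chrom, binning$bins$start)
    hit <- match(paste(df$chrom, df$start), key_bin)
    if (anyNA(hit)) stop("bedGraph interval does not match the binning")
    values[hit] <- df$value
  }
  structure(list(values = values, binning = binning), class = "EigenTrack")
}
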