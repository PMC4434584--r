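#' Per-distance diagonal sums of a contact map
#'
#' For each genomic separation (in bins), the sum of intrachromosomal
#' matrix entries at that separation, aggregated over all chromosomes, with
#' each unordered pair counted once. Also reports the number of locus pairs
#' per separation and the corresponding raw read support (used by the error
#' model of [compression_coefficients()]).
#'
#' @param map A `ContactMap`.
#' @return Data frame with `separation` (bins), `sum`, `raw_sum`, `n_pairs`.
#' @export
diagonal_sums <- function(map) {
  binning <- map$binning
  max_nb <- max(table(binning$bin_chrom))
  seps <- 0:(max_nb - 1)
  s <- rs <- np <- numeric(length(seps))
  for (ci in seq_len(nrow(binning$chromosomes))) {
    idx <- chrom_bins(binning, ci)
    nb <- length(idx)
    A <- map$counts[idx, idx, drop = FALSE]
    R <- map$raw[idx, idx, drop = FALSE]
    for (d in 0:(nb - 1)) {
      k <- seq_len(nb - d)
      ii <- cbind(k, k + d)
      s[d + 1] <- s[d + 1] + sum(A[ii])
      rs[d + 1] <- rs[d + 1] + sum(R[ii])
      np[d + 1] <- np[d + 1] + (nb - d)
    }
  }
  data.frame(separation = seps, sum = s, raw_sum = rs, n_pairs = np)
}

#' Compression coefficients between two maps
#'
#' For every intrachromosomal separation `j`, the coefficient
#' `K_j = target_j / source_j` rescales the source map's per-distance
#' contact mass onto the target's (the "compression" of one genome to the
#' other's packaging density). The relative error of each coefficient
#' combines the shot-noise errors `sqrt(K)/K` of the numerator and
#' denominator raw read supports in quadrature,
#' `sqrt(1/R_target + 1/R_source)`; coefficients with error above
#' `error_gate` (default 5%) are not applied. Separations where the source
#' sum is zero but the target is not are skipped with a warning.
#'
#' @param target,source Corrected `ContactMap`s on one binning (target =
#'   the map whose P(s) is to be matched).
#' @param error_gate Maximum relative error for a coefficient to be applied.
#' @return A `CompressionCoefficients`: data.frame with `separation`, `K`,
#'   `error`, `applied`, `target_sum`, `source_sum`.
#' @export
compression_coefficients <- function(target, source, error_gate = 0.05) {
  stopifnot_same_binning(target$binning, source$binning)
  dt <- diagonal_sums(target)
  ds <- diagonal_sums(source)
  K <- ifelse(ds$sum > 0, dt$sum / ds$sum, NA_real_)
  if (any(is.na(K) & dt$sum > 0)) {
    warning(sprintf(
      "%d separation(s) with zero source mass but nonzero target mass skipped",
      sum(is.na(K) & dt$sum > 0)))
  }
  err <- ifelse(dt$raw_sum > 0 & ds$raw_sum > 0,
                sqrt(1 / dt$raw_sum + 1 / ds$raw_sum), Inf)
  applied <- !is.na(K) & K > 0 & err <= error_gate
  out <- data.frame(separation = dt$separation, K = K, error = err,
                    applied = applied,
                    target_sum = dt$sum, source_sum = ds$sum)
  class(out) <- c("CompressionCoefficients", class(out))
  out
}

#' Apply compression coefficients to a map
#'
#' Multiplies every intrachromosomal entry at separation `j` by `K_j` where
#' the coefficient was applied (unapplied separations keep coefficient 1),
#' leaves trans entries untouched, and finally rescales the whole matrix
#' uniformly so its total equals the source's original total. Within each
#' separation the ratios between entries are preserved exactly.
#'
#' @param source A `ContactMap` (the map being compressed).
#' @param coeffs A `CompressionCoefficients` computed against this binning.
#' @param rescale Rescale the output total back to the source total
#'   (default TRUE; FALSE exposes the pre-rescale matrix whose applied
#'   diagonal sums equal the target's).
#' @return A `ContactMap` with `value_kind = "corrected"`, carrying the
#'   source's raw support.
#' @export
apply_compression <- function(source, coeffs, rescale = TRUE) {
  binning <- source$binning
  k_of <- rep(1, max(coeffs$separation) + 1)
  k_of[coeffs$separation[coeffs$applied] + 1] <- coeffs$K[coeffs$applied]
  x <- source$counts
  for (ci in seq_len(nrow(binning$chromosomes))) {
    idx <- chrom_bins(binning, ci)
    d <- abs(outer(idx, idx, "-"))
    x[idx, idx] <- x[idx, idx] * k_of[d + 1]
  }
  if (rescale) {
    tot <- sum(x)
    if (tot > 0) x <- x * (source$total / tot)
  }
  contact_map(binning, x, value_kind = "corrected", raw = source$raw,
              masked = source$masked)
}
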