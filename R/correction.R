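#' Iterative correction of a contact map
#'
#' Removes multiplicative per-bin biases by symmetric matrix balancing
#' (Sinkhorn-style): the corrected matrix is `raw[i,j] / (bias[i] * bias[j])`
#' with biases chosen so that every unmasked bin has the same row sum. The
#' balanced matrix is finally rescaled globally so that its total equals the
#' input total; the rescale is folded into the biases so the bias identity
#' holds exactly.
#'
#' Bins with a zero marginal are always masked before balancing; an optional
#' bottom-coverage percentile mask removes additional low-coverage bins.
#' Masked bins end up with all-zero rows and columns.
#'
#' @param map A `ContactMap` (normally raw; passing a corrected map is
#'   allowed and is a near no-op, which is how idempotence is checked).
#' @param tolerance Convergence threshold: the maximum relative deviation of
#'   unmasked row sums from their mean.
#' @param max_iter Maximum balancing iterations; non-convergence is an error
#'   reporting the final residual.
#' @param mask_percentile Fraction (0-1) of the lowest-coverage unmasked bins
#'   additionally masked before balancing; default 0.
#' @return A `CorrectedMap` (a `ContactMap` with `value_kind = "corrected"`)
#'   carrying `biases` (per-bin multipliers, NA for masked bins) and
#'   `convergence` (list of `iterations`, `residual`).
#' @examples
#' gb <- genome_binning(c(chrA = 5e6), 1e6)
#' m <- contact_map(gb, matrix(1, 5, 5))
#' cm <- iterative_correction(m)
#' range(rowSums(cm$counts))
#' @export
iterative_correction <- function(map, tolerance = 1e-6, max_iter = 200,
                                 mask_percentile = 0) {
  x <- map$counts
  n <- nrow(x)
  marg <- rowSums(x)
  masked <- map$masked | marg == 0
  if (mask_percentile > 0) {
    pos <- marg[!masked]
    if (length(pos)) {
      thr <- stats::quantile(pos, mask_percentile, names = FALSE)
      masked <- masked | marg < thr
    }
  }
  if (all(masked)) stop("all bins are masked; nothing to balance")
  x[masked, ] <- 0
  x[, masked] <- 0

  bias <- rep(1, n)
  free <- !masked
  iterations <- 0L
  residual <- Inf
  repeat {
    s <- rowSums(x)
    target <- mean(s[free])
    if (target == 0) stop("all unmasked bins have zero coverage")
    residual <- max(abs(s[free] / target - 1))
    if (residual < tolerance) break
    if (iterations >= max_iter) {
      stop(sprintf(
        "iterative correction did not converge in %d iterations (residual %.3g)",
        max_iter, residual))
    }
    d <- s / target
    d[!free] <- 1
    x <- x / outer(d, d)
    bias <- bias * d
    iterations <- iterations + 1L
  }

  # rescale to the input total, folding the factor into the biases
  tot <- sum(x)
  scale <- map$total / tot
  x <- x * scale
  bias <- bias / sqrt(scale)
  bias[masked] <- NA_real_

  out <- contact_map(map$binning, x, value_kind = "corrected",
                     raw = map$raw, masked = masked)
  out$biases <- bias
  out$convergence <- list(iterations = iterations, residual = residual)
  class(out) <- c("CorrectedMap", class(out))
  out
}

#' Joint low-coverage mask for one or two maps
#'
#' Flags bins whose combined raw marginal falls in the bottom coverage
#' percentile (plus all zero-marginal bins). When two maps are given the
#' marginals are summed, so both maps share one mask and a bin borderline
#' in one map cannot be masked in one map only - a mask mismatch would
#' masquerade as a huge regional difference.
#'
#' @param map_a A `ContactMap`.
#' @param map_b Optional second `ContactMap` on the same binning.
#' @param percentile Fraction (0-1) of lowest-coverage bins to mask.
#' @return Logical per-bin vector (TRUE = masked).
#' @export
mask_low_coverage <- function(map_a, map_b = NULL, percentile = 0.02) {
  marg <- rowSums(map_a$raw)
  if (!is.null(map_b)) {
    stopifnot_same_binning(map_a$binning, map_b$binning)
    marg <- marg + rowSums(map_b$raw)
  }
  masked <- marg == 0
  if (percentile > 0 && any(!masked)) {
    thr <- stats::quantile(marg[!masked], percentile, names = FALSE)
    masked <- masked | marg < thr
  }
  masked
}

#' Write per-bin balancing biases as a sidecar TSV
#' @param corrected A `CorrectedMap`.
#' @param path Output path.
#' @export
write_biases <- function(corrected, path) {
  df <- corrected$binning$bins
  utils::write.table(
    data.frame(chrom = df$chrom, start = df$start, end = df$end,
               bias = sprintf("%.17g", corrected$biases)),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
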