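# Independent brute-force oracles and tiny fixture builders shared across
# the suite. Oracles deliberately avoid the package's own code paths.

tiny_binning <- function(chrom_bins, bin_size = 1e6) {
  sizes <- stats::setNames(chrom_bins * bin_size,
                           paste0("chr", seq_along(chrom_bins)))
  genome_binning(sizes, bin_size)
}

tiny_map <- function(counts, chrom_bins = nrow(counts), ...) {
  contact_map(tiny_binning(chrom_bins), counts, ...)
}

random_symmetric_map <- function(n, lambda = 20, seed = 1, chrom_bins = n) {
  set.seed(seed)
  x <- matrix(rpois(n * n, lambda), n)
  x[lower.tri(x)] <- t(x)[lower.tri(x)]
  tiny_map(x, chrom_bins = chrom_bins)
}

# alternating row/column normalization (classic Sinkhorn), independent of
# the package's symmetric balancing update
oracle_sinkhorn <- function(mat, iters = 5000) {
  x <- mat
  for (k in seq_len(iters)) {
    x <- x / rowSums(x)
    x <- t(t(x) / colSums(x))
  }
  x
}

oracle_euclid <- function(A, B, chrom_of) {
  n <- nrow(A)
  out <- numeric(n)
  for (i in seq_len(n)) {
    s <- 0
    for (j in seq_len(n)) {
      if (j != i && chrom_of[j] == chrom_of[i]) s <- s + (A[i, j] - B[i, j])^2
    }
    out[i] <- sqrt(s)
  }
  out
}

# textbook correlation formulas over cis partners, by explicit loops
oracle_bin_cor <- function(A, B, chrom_of, method = "pearson") {
  n <- nrow(A)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    js <- setdiff(which(chrom_of == chrom_of[i]), i)
    x <- A[i, js]; y <- B[i, js]
    if (method == "spearman") { x <- rank(x); y <- rank(y) }
    mx <- mean(x); my <- mean(y)
    sx <- sqrt(sum((x - mx)^2)); sy <- sqrt(sum((y - my)^2))
    if (sx == 0 || sy == 0) next
    out[i] <- sum((x - mx) * (y - my)) / (sx * sy)
  }
  out
}

oracle_diagonal_sums <- function(counts, chrom_of) {
  n <- nrow(counts)
  sums <- list()
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (chrom_of[i] != chrom_of[j]) next
      d <- as.character(j - i)
      sums[[d]] <- (if (is.null(sums[[d]])) 0 else sums[[d]]) + counts[i, j]
    }
  }
  sums
}

# standard normal upper tail by numeric integration (independent of pnorm)
oracle_tail <- function(z) {
  stats::integrate(function(t) exp(-t^2 / 2) / sqrt(2 * pi), abs(z), Inf,
                   rel.tol = 1e-12)$value
}

oracle_interchrom_expected <- function(S, T_total, i, j) {
  unname(0.5 * (S[i] * S[j] / (T_total - S[i]) +
                S[i] * S[j] / (T_total - S[j])))
}

# correct + depth-match a synthetic pair the way the pipeline does
corrected_pair <- function(pair, mask_percentile = 0) {
  if (mask_percentile > 0) {
    m <- mask_low_coverage(pair$map_a, pair$map_b, mask_percentile)
    pair$map_a$masked <- m
    pair$map_b$masked <- m
  }
  ca <- iterative_correction(pair$map_a)
  cb <- rescale_total(iterative_correction(pair$map_b), ca$total)
  list(a = ca, b = cb)
}

n_significant <- function(tt) {
  sum(tt$class %in% c("significant", "significant_2fold"))
}
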