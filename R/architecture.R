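#' Contact probability versus genomic distance, P(s)
#'
#' Averages intrachromosomal contact frequency over all locus pairs at each
#' genomic separation, aggregated across chromosomes. With
#' `scheme = "per_diagonal"` every bin-separation is its own distance bin;
#' with `scheme = "log"` separations are pooled into geometric bins with the
#' given ratio (display binning).
#'
#' @param map A `ContactMap`.
#' @param scheme `"per_diagonal"` or `"log"`.
#' @param log_ratio Geometric bin ratio for `scheme = "log"` (default 1.3).
#' @return A `ScalingCurve`: data.frame with `distance` (bp, geometric bin
#'   centers), `prob` (mean contact frequency per locus pair) and `n_pairs`.
#' @export
ps_curve <- function(map, scheme = c("per_diagonal", "log"), log_ratio = 1.3) {
  scheme <- match.arg(scheme)
  binning <- map$binning
  sums <- diagonal_sums(map)
  sums <- sums[sums$separation > 0, , drop = FALSE]
  if (nrow(sums) == 0 || all(sums$sum == 0)) stop("no intrachromosomal contacts")
  d_bp <- sums$separation * binning$bin_size

  if (scheme == "per_diagonal") {
    curve <- data.frame(distance = d_bp,
                        prob = sums$sum / sums$n_pairs,
                        n_pairs = sums$n_pairs)
  } else {
    edges <- log_ratio^(0:ceiling(log(max(sums$separation)) / log(log_ratio)))
    grp <- findInterval(sums$separation, edges)
    tot <- tapply(sums$sum, grp, sum)
    np <- tapply(sums$n_pairs, grp, sum)
    ctr <- tapply(d_bp, grp, function(v) exp(mean(log(v))))
    curve <- data.frame(distance = as.numeric(ctr),
                        prob = as.numeric(tot) / as.numeric(np),
                        n_pairs = as.numeric(np))
  }
  curve <- curve[order(curve$distance), , drop = FALSE]
  rownames(curve) <- NULL
  class(curve) <- c("ScalingCurve", class(curve))
  curve
}

#' Fit a power law to a scaling curve
#'
#' Ordinary least squares of `log10 P` on `log10 s` over the fit range;
#' the slope is the (signed) scaling exponent. Nonpositive frequencies in
#' range are excluded with a warning. The default range drops the first
#' diagonal and distances supported by fewer than `min_pairs` locus pairs.
#'
#' @param curve A `ScalingCurve`.
#' @param fit_range Numeric `c(min_bp, max_bp)` or `NULL` for the default.
#' @param min_pairs Minimum pair support per point for the default range.
#' @return A `PowerLawFit`: list with `exponent` (slope), `se` (regression
#'   standard error of the slope), `fit_range`, `n_points`, `intercept`.
#' @export
fit_power_law <- function(curve, fit_range = NULL, min_pairs = 100) {
  keep <- rep(TRUE, nrow(curve))
  if (is.null(fit_range)) {
    keep <- curve$n_pairs >= min_pairs & curve$distance > min(curve$distance)
    if (sum(keep & curve$prob > 0) < 3) {
      # small maps never reach min_pairs; fall back to all usable diagonals
      keep <- curve$distance > min(curve$distance)
    }
  } else {
    keep <- curve$distance >= fit_range[1] & curve$distance <= fit_range[2]
  }
  pos <- curve$prob > 0
  if (any(keep & !pos)) {
    warning(sprintf("%d nonpositive curve points excluded from the fit",
                    sum(keep & !pos)))
  }
  keep <- keep & pos
  if (sum(keep) < 3) stop("fewer than 3 positive curve points in the fit range")
  lx <- log10(curve$distance[keep])
  ly <- log10(curve$prob[keep])
  fit <- stats::lm(ly ~ lx)
  sm <- summary(fit)$coefficients
  out <- list(exponent = unname(sm["lx", "Estimate"]),
              se = unname(sm["lx", "Std. Error"]),
              intercept = unname(sm["(Intercept)", "Estimate"]),
              fit_range = range(curve$distance[keep]),
              n_points = sum(keep))
  class(out) <- "PowerLawFit"
  out
}

#' @export
print.PowerLawFit <- function(x, ...) {
  cat(sprintf("PowerLawFit: P(s) ~ s^%.4g (se %.2g, %d points, %s-%s bp)\n",
              x$exponent, x$se, x$n_points,
              format(x$fit_range[1], big.mark = ","),
              format(x$fit_range[2], big.mark = ",")))
  invisible(x)
}

#' Per-distance ratio of two scaling curves
#'
#' @param curve_a,curve_b `ScalingCurve`s on the same distance bins.
#' @return Data frame with `distance` and `ratio` (`a / b` where both are
#'   positive, NA elsewhere).
#' @export
ps_ratio <- function(curve_a, curve_b) {
  if (nrow(curve_a) != nrow(curve_b) ||
      any(curve_a$distance != curve_b$distance)) {
    stop("curves are not on shared distance bins")
  }
  ok <- curve_a$prob > 0 & curve_b$prob > 0
  data.frame(distance = curve_a$distance,
             ratio = ifelse(ok, curve_a$prob / curve_b$prob, NA_real_))
}

#' Intra- to interchromosomal contact ratio
#'
#' For each chromosome, the total of its intrachromosomal contacts divided
#' by the total of its contacts with all other chromosomes, plus the
#' genome-wide aggregate (total cis over total trans). Chromosomes with no
#' trans contacts get an infinite ratio with a warning.
#'
#' @param map A `ContactMap`.
#' @return List with `per_chromosome` (data.frame `chrom`, `cis`, `trans`,
#'   `ratio`) and `genome_wide`.
#' @export
cis_trans_ratio <- function(map) {
  binning <- map$binning
  chroms <- binning$chromosomes$name
  cis <- trans <- numeric(length(chroms))
  for (ci in seq_along(chroms)) {
    idx <- chrom_bins(binning, ci)
    cis[ci] <- sum(map$counts[idx, idx])
    trans[ci] <- sum(map$counts[idx, -idx])
  }
  if (any(trans == 0)) {
    warning("chromosome(s) with zero trans contacts: infinite cis/trans ratio")
  }
  per <- data.frame(chrom = chroms, cis = cis, trans = trans,
                    ratio = ifelse(trans > 0, cis / trans, Inf))
  list(per_chromosome = per,
       genome_wide = if (sum(trans) > 0) sum(cis) / sum(trans) else Inf)
}

#' Interchromosomal contact enrichment matrix
#'
#' Observed/expected trans contact frequencies per chromosome pair. With
#' `S_i` the total trans contacts of chromosome `i`, `S_ij` the contacts
#' between `i` and `j` and `T` the genome total of trans contacts (each
#' unordered pair counted once), the expected value is the symmetrized
#' `0.5 * (S_i*S_j/(T - S_i) + S_i*S_j/(T - S_j))`; `as_printed = TRUE`
#' instead repeats `(T - S_i)` in both terms, reproducing the asymmetric
#' published form for audit.
#'
#' @param map A `ContactMap` with at least 3 chromosomes and trans contacts.
#' @param as_printed Use the asymmetric audit form of the expectation.
#' @return An `InterchromMatrix`: list with matrices `observed`, `expected`,
#'   `enrichment` (chromosome x chromosome, NA diagonal), vector `S` and
#'   total `T`.
#' @export
interchrom_enrichment <- function(map, as_printed = FALSE) {
  binning <- map$binning
  nc <- nrow(binning$chromosomes)
  if (nc < 3) stop("interchromosomal enrichment needs at least 3 chromosomes")
  S_ij <- matrix(0, nc, nc, dimnames = list(binning$chromosomes$name,
                                            binning$chromosomes$name))
  for (ci in seq_len(nc)) {
    idx_i <- chrom_bins(binning, ci)
    for (cj in seq_len(nc)) {
      if (cj <= ci) next
      idx_j <- chrom_bins(binning, cj)
      S_ij[ci, cj] <- S_ij[cj, ci] <- sum(map$counts[idx_i, idx_j])
    }
  }
  S <- rowSums(S_ij)
  if (any(S == 0)) stop("chromosome with zero trans contacts")
  T_total <- sum(S_ij[upper.tri(S_ij)])
  expected <- matrix(NA_real_, nc, nc, dimnames = dimnames(S_ij))
  for (ci in seq_len(nc)) {
    for (cj in seq_len(nc)) {
      if (ci == cj) next
      den2 <- if (as_printed) T_total - S[ci] else T_total - S[cj]
      expected[ci, cj] <- 0.5 * (S[ci] * S[cj] / (T_total - S[ci]) +
                                 S[ci] * S[cj] / den2)
    }
  }
  enrichment <- S_ij / expected
  diag(enrichment) <- NA_real_
  out <- list(observed = S_ij, expected = expected, enrichment = enrichment,
              S = S, T = T_total)
  class(out) <- "InterchromMatrix"
  out
}

#' Correlation of interchromosomal enrichment with chromosome length difference
#'
#' Pearson correlation, over all chromosome pairs, between the enrichment
#' (or raw observed contacts) and the absolute difference of the two
#' chromosome lengths.
#'
#' @param interchrom An `InterchromMatrix`.
#' @param binning The `GenomeBinning` providing chromosome lengths.
#' @param use `"enrichment"` (default) or `"observed"`.
#' @return Pearson r.
#' @export
length_diff_correlation <- function(interchrom, binning,
                                    use = c("enrichment", "observed")) {
  use <- match.arg(use)
  nc <- nrow(interchrom$enrichment)
  if (nc < 3) stop("need at least 3 chromosome pairs")
  len <- binning$chromosomes$length
  ut <- upper.tri(interchrom$enrichment)
  v <- interchrom[[use]][ut]
  dl <- abs(outer(len, len, "-"))[ut]
  if (stats::sd(v) == 0) stop("constant enrichment: correlation undefined")
  stats::cor(v, dl)
}

#' Write a scaling curve (TSV)
#' @param curve A `ScalingCurve`.
#' @param path Output path.
#' @export
write_scaling_curve <- function(curve, path) {
  utils::write.table(as.data.frame(curve), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
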