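#' Per-bin Euclidean distance between two contact maps
#'
#' For each bin `i`, the Euclidean distance between its contact vectors in
#' the two maps, restricted to intrachromosomal partners `j != i`:
#' `E_i = sqrt( sum_j (a_ij - b_ij)^2 )`. A larger distance marks a bin
#' whose contact profile differs more between the two maps.
#'
#' @param map_a,map_b `ContactMap`s on the same binning (normally
#'   iteratively corrected and rescaled to equal totals so the metric is
#'   depth-comparable; see [bin_difference_table()]).
#' @return Numeric per-bin profile.
#' @export
bin_euclidean_profile <- function(map_a, map_b) {
  stopifnot_same_binning(map_a$binning, map_b$binning)
  binning <- map_a$binning
  out <- numeric(binning$n_bins)
  D2 <- (map_a$counts - map_b$counts)^2
  for (ci in seq_len(nrow(binning$chromosomes))) {
    idx <- chrom_bins(binning, ci)
    block <- D2[idx, idx, drop = FALSE]
    diag(block) <- 0
    out[idx] <- sqrt(rowSums(block))
  }
  out
}

#' Per-bin Pearson and Spearman correlation between two contact maps
#'
#' Correlates each bin's intrachromosomal contact vector (partners
#' `j != i`) between the two maps. Bins whose vector is constant in either
#' map get NA and are flagged.
#'
#' @param map_a,map_b `ContactMap`s on the same binning.
#' @return Data frame with per-bin columns `pearson`, `spearman`, and
#'   `undefined` (constant-row flag).
#' @export
bin_correlation_profile <- function(map_a, map_b) {
  stopifnot_same_binning(map_a$binning, map_b$binning)
  binning <- map_a$binning
  n <- binning$n_bins
  pe <- rep(NA_real_, n); sp <- rep(NA_real_, n)
  for (ci in seq_len(nrow(binning$chromosomes))) {
    idx <- chrom_bins(binning, ci)
    if (length(idx) < 4) next  # < 3 partners after dropping self
    A <- map_a$counts[idx, idx, drop = FALSE]
    B <- map_b$counts[idx, idx, drop = FALSE]
    for (k in seq_along(idx)) {
      x <- A[k, -k]; y <- B[k, -k]
      if (stats::sd(x) == 0 || stats::sd(y) == 0) next
      pe[idx[k]] <- stats::cor(x, y)
      sp[idx[k]] <- stats::cor(x, y, method = "spearman")
    }
  }
  data.frame(pearson = pe, spearman = sp, undefined = !is.finite(pe))
}

#' Flag poor bins from a split-half reference correlation profile
#'
#' Poor bins are those whose split-half correlation `C_i` satisfies
#' `C_i < M - SD`, where `M` and `SD` are the median and standard deviation
#' of `C_i` over all bins; one bin upstream and downstream of each poor bin
#' (within its chromosome) is flagged as a flank. All flagged bins are
#' excluded from candidate ranking downstream.
#'
#' @param c_i Per-bin reference correlations (typically the Pearson column
#'   of [bin_correlation_profile()] run on the two [thin_split()] halves of
#'   a reference map).
#' @param binning The `GenomeBinning` (needed to stop flanks at chromosome
#'   edges).
#' @return Data frame with logical columns `poor` and `flank`.
#' @export
poor_bin_filter <- function(c_i, binning) {
  if (sum(is.finite(c_i)) < 3) stop("fewer than 3 finite reference correlations")
  M <- stats::median(c_i, na.rm = TRUE)
  SD <- stats::sd(c_i, na.rm = TRUE)
  poor <- is.finite(c_i) & c_i < M - SD
  poor[!is.finite(c_i)] <- TRUE  # undefined reference bins are unusable too
  flank <- rep(FALSE, length(c_i))
  w <- which(poor)
  for (i in w) {
    for (nb in c(i - 1L, i + 1L)) {
      if (nb >= 1L && nb <= length(c_i) &&
          binning$bin_chrom[nb] == binning$bin_chrom[i] && !poor[nb]) {
        flank[nb] <- TRUE
      }
    }
  }
  data.frame(poor = poor, flank = flank)
}

#' Three-metric per-bin difference table for two maps
#'
#' Computes, for every bin, the Euclidean distance, Pearson and Spearman
#' correlations, and the eigenvector distance (perpendicular distance of
#' the bin's (E1_a, E1_b) dot to the regression line) between the two maps,
#' and attaches exclusion flags from a reference split-half profile when
#' given. Ranks per metric (1 = most different: largest Euclidean distance,
#' smallest Pearson correlation, largest eigen-distance) are assigned over
#' non-excluded bins only, ties broken by ascending bin index.
#'
#' @param map_a,map_b Corrected `ContactMap`s on one binning, equal totals.
#' @param e1_a,e1_b Optional precomputed `EigenTrack`s (computed from the
#'   maps when omitted; then the maps must be `CorrectedMap`s).
#' @param reference_c Optional per-bin reference correlation profile for the
#'   poor-bin filter (see [poor_bin_filter()]).
#' @param line Regression flavor passed to [compare_e1()].
#' @return A `BinDifferenceTable`: data.frame with BED coordinates, the
#'   metrics, `poor`/`flank`/`excluded` flags and `rank_euclid`,
#'   `rank_pearson`, `rank_eigen`.
#' @export
bin_difference_table <- function(map_a, map_b, e1_a = NULL, e1_b = NULL,
                                 reference_c = NULL, line = "ols") {
  stopifnot_same_binning(map_a$binning, map_b$binning)
  binning <- map_a$binning
  if (is.null(e1_a)) e1_a <- compute_e1(map_a)
  if (is.null(e1_b)) e1_b <- compute_e1(map_b)

  eu <- bin_euclidean_profile(map_a, map_b)
  co <- bin_correlation_profile(map_a, map_b)
  ed <- compare_e1(e1_a, e1_b, line = line)

  tab <- data.frame(
    chrom = binning$bins$chrom,
    start = binning$bins$start,
    end = binning$bins$end,
    euclid = eu,
    pearson = co$pearson,
    spearman = co$spearman,
    eigen_dist = ed$distance
  )
  if (!is.null(reference_c)) {
    fl <- poor_bin_filter(reference_c, binning)
    tab$poor <- fl$poor
    tab$flank <- fl$flank
  } else {
    tab$poor <- FALSE
    tab$flank <- FALSE
  }
  tab$excluded <- tab$poor | tab$flank
  tab <- add_metric_ranks(tab)
  class(tab) <- c("BinDifferenceTable", class(tab))
  tab
}

# rank 1 = most different; NA metrics and excluded bins carry no rank
add_metric_ranks <- function(tab) {
  rank_of <- function(metric, decreasing) {
    r <- rep(NA_real_, nrow(tab))
    use <- which(!tab$excluded & is.finite(metric))
    key <- if (decreasing) -metric[use] else metric[use]
    r[use] <- rank(key, ties.method = "first")
    r
  }
  tab$rank_euclid <- rank_of(tab$euclid, decreasing = TRUE)
  tab$rank_pearson <- rank_of(tab$pearson, decreasing = FALSE)
  tab$rank_eigen <- rank_of(tab$eigen_dist, decreasing = TRUE)
  tab
}

#' Select and intersect top-ranked candidate bins
#'
#' Takes, per metric, the `n` highest-ranked (most different) non-excluded
#' bins of `table` as candidates, removes from each set any bin that also
#' sits in the reference table's top-`n` for the same metric (region-specific
#' bias control), and returns the intersection of the three filtered sets,
#' together with the expected overlap under random selection.
#'
#' @param table A `BinDifferenceTable` comparing the two maps of interest.
#' @param reference_table Optional `BinDifferenceTable` computed between two
#'   split halves of a reference map; `NULL` skips the exclusion step.
#' @param n Candidate set size per metric (default 100).
#' @return A `CandidateSet`: list with the three filtered bin-index sets
#'   (`euclid`, `pearson`, `eigen`; 1-based), `intersection`, the
#'   post-filtering sizes `n_eucl`, `n_p`, `n_e1`, total bins `n_t`, and
#'   `expected` (= `n_eucl*n_p*n_e1/n_t^2`).
#' @export
select_candidates <- function(table, reference_table = NULL, n = 100) {
  avail <- sum(!table$excluded)
  if (n > avail) stop(sprintf("n = %d exceeds the %d available bins", n, avail))
  top <- function(tab, rank_col) which(!is.na(tab[[rank_col]]) & tab[[rank_col]] <= n)
  sets <- list(euclid = top(table, "rank_euclid"),
               pearson = top(table, "rank_pearson"),
               eigen = top(table, "rank_eigen"))
  if (!is.null(reference_table)) {
    stopifnot(nrow(reference_table) == nrow(table))
    ref <- list(euclid = top(reference_table, "rank_euclid"),
                pearson = top(reference_table, "rank_pearson"),
                eigen = top(reference_table, "rank_eigen"))
    sets <- Map(setdiff, sets, ref)
  }
  inter <- Reduce(intersect, sets)
  n_t <- nrow(table)
  out <- list(euclid = sets$euclid, pearson = sets$pearson, eigen = sets$eigen,
              intersection = sort(inter),
              n_eucl = length(sets$euclid), n_p = length(sets$pearson),
              n_e1 = length(sets$eigen), n_t = n_t,
              expected = expected_overlap(length(sets$euclid),
                                          length(sets$pearson),
                                          length(sets$eigen), n_t))
  class(out) <- "CandidateSet"
  out
}

#' @export
print.CandidateSet <- function(x, ...) {
  cat(sprintf(
    "CandidateSet: |Eucl|=%d |Pearson|=%d |E1|=%d of %d bins; intersection %d (expected %.4g)\n",
    x$n_eucl, x$n_p, x$n_e1, x$n_t, length(x$intersection), x$expected))
  invisible(x)
}

#' Expected size of a three-way random candidate overlap
#'
#' Under independent random selection of three candidate sets of sizes
#' `n_eucl`, `n_p`, `n_e1` out of `n_t` bins, the expected size of their
#' intersection is `n_eucl * n_p * n_e1 / n_t^2`.
#'
#' @param n_eucl,n_p,n_e1 Post-filtering candidate set sizes.
#' @param n_t Total number of bins.
#' @return Expected overlap (a real number).
#' @examples
#' expected_overlap(100, 100, 100, 2308)
#' @export
expected_overlap <- function(n_eucl, n_p, n_e1, n_t) {
  if (n_t == 0) stop("n_t must be positive")
  if (any(c(n_eucl, n_p, n_e1) > n_t)) stop("set sizes cannot exceed n_t")
  n_eucl * n_p * n_e1 / n_t^2
}

#' Build the split-half reference difference table
#'
#' Thins a raw reference map into two half-depth replicates, corrects both,
#' and computes the [bin_difference_table()] between them. Its Pearson
#' column is the poor-bin reference profile `C_i`; its ranks are the
#' bias-exclusion sets used by [select_candidates()].
#'
#' Any coverage mask on the reference map is deliberately dropped first:
#' the split-half correlation distribution must keep its genuinely poor
#' tail, because the `C_i < M - SD` rule only separates poor bins from the
#' good bulk when the standard deviation is inflated by that tail. (With
#' low-coverage bins masked away, `M - SD` would cut into the noise bulk
#' of perfectly good bins.)
#'
#' @param reference_map A raw `ContactMap`.
#' @param seed Seed for the binomial thinning.
#' @param line Regression flavor for the eigen distance.
#' @return List with `table` (a `BinDifferenceTable`), `c_i` (its Pearson
#'   profile) and the two corrected halves.
#' @export
reference_difference_table <- function(reference_map, seed = 1L, line = "ols") {
  reference_map$masked <- rep(FALSE, reference_map$binning$n_bins)
  halves <- thin_split(reference_map, seed = seed)
  h1 <- iterative_correction(halves[[1]])
  h2 <- iterative_correction(halves[[2]])
  co <- bin_correlation_profile(h1, h2)
  tab <- bin_difference_table(h1, h2, reference_c = co$pearson, line = line)
  list(table = tab, c_i = co$pearson, half1 = h1, half2 = h2)
}

#' Write a difference table as TSV keyed by BED coordinates
#' @param table A `BinDifferenceTable`.
#' @param path Output path.
#' @export
write_difference_table <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
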