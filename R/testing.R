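#' Contact probability of one bin pair under the uniform model
#'
#' The probability of a contact is `P = m / M`, where `m` is the support of
#' the pair and `M` is the total support of the map, both counted over
#' mappable contacts only (raw support of more than one read). An
#' unmappable pair contributes `m = 0` and is excluded from `M`.
#'
#' @param map A `ContactMap`; supports are its `counts` values (corrected
#'   pseudo-counts after iterative correction), gated by the raw-count
#'   mappability rule.
#' @param i,j 1-based bin indices.
#' @return List with `m`, `M`, `P`.
#' @export
contact_probability <- function(map, i, j) {
  mp <- mappable_matrix(map)
  M <- total_mappable_support(map, mp)
  if (M == 0) stop("map has no mappable contacts")
  m <- if (mp[i, j]) map$counts[i, j] else 0
  list(m = m, M = M, P = m / M)
}

mappable_matrix <- function(map) map$raw >= 2

# total support over mappable unordered pairs (i <= j), each counted once
total_mappable_support <- function(map, mp = mappable_matrix(map)) {
  ut <- upper.tri(map$counts, diag = TRUE)
  sum(map$counts[ut & mp])
}

#' Normal-approximation gate for a binomial proportion
#'
#' A contact enters the two-proportion test only when the binomial
#' distribution of its support is well approximated by a normal:
#' `M * P * (1 - P) > 9`.
#'
#' @param M Total support.
#' @param P Contact probability.
#' @return Logical (vectorized).
#' @examples
#' normal_approx_ok(1000, 0.5)  # TRUE
#' normal_approx_ok(100, 0.01)  # FALSE
#' @export
normal_approx_ok <- function(M, P) {
  M * P * (1 - P) > 9
}

#' Two-proportion z-test for one contact
#'
#' Tests the null hypothesis that a contact has the same probability in two
#' datasets, using the unpooled normal approximation:
#' `z = (P_a - P_b) / sqrt(P_a(1-P_a)/M_a + P_b(1-P_b)/M_b)` and the
#' conventional two-sided p-value `p = 2 * (1 - pnorm(|z|))`. The
#' `as_printed` mode instead returns `2 * pnorm(|z|) - 1` (the confidence
#' level rather than a tail probability), kept for audit only.
#'
#' @param P_a,P_b Contact probabilities.
#' @param M_a,M_b Total supports.
#' @param as_printed Use the confidence-level form instead of the
#'   conventional two-sided p-value.
#' @return List with `z` and `p` (vectorized).
#' @export
two_proportion_pvalue <- function(P_a, M_a, P_b, M_b, as_printed = FALSE) {
  se <- sqrt(P_a * (1 - P_a) / M_a + P_b * (1 - P_b) / M_b)
  if (any(se == 0)) stop("zero standard error: degenerate proportions")
  z <- (P_a - P_b) / se
  p <- if (as_printed) 2 * stats::pnorm(abs(z)) - 1 else 2 * stats::pnorm(-abs(z))
  list(z = z, p = p)
}

#' Bonferroni q-values
#'
#' Multiplies each p-value by the number of hypotheses actually tested,
#' capped at 1.
#'
#' @param p_values Numeric vector of p-values.
#' @param n_tests Number of tests (default: `length(p_values)`).
#' @return q-values.
#' @export
bonferroni <- function(p_values, n_tests = length(p_values)) {
  pmin(1, p_values * n_tests)
}

#' Differential test of all contacts between two maps
#'
#' Runs the uniform-probability two-proportion test over every bin pair that
#' is mappable (raw support > 1 read) in both datasets and passes the
#' normal-approximation gate in both, then applies Bonferroni correction
#' over the gated tests and classifies each contact.
#'
#' @param map_a,map_b `ContactMap`s on one binning (normally corrected, with
#'   raw support carried along for the mappability rule).
#' @param q_threshold Significance threshold on q-values (default 0.05).
#' @param fold Ratio threshold for the `significant_2fold` class (default 2).
#' @param mappable `"both"` (contact must be mappable in each dataset;
#'   default) or `"either"`.
#' @param as_printed Passed to [two_proportion_pvalue()].
#' @return A `ContactTestTable`: data.frame of all tested-or-untestable
#'   mappable pairs with columns `i`, `j` (0-based), `P_a`, `P_b`, `M_a`,
#'   `M_b`, `z`, `p`, `q`, `ratio`, `class`; attributes `n_tests`, `counts`
#'   (per-class tallies) and `M_a`/`M_b`.
#' @export
test_contacts <- function(map_a, map_b, q_threshold = 0.05, fold = 2,
                          mappable = c("both", "either"), as_printed = FALSE) {
  mappable <- match.arg(mappable)
  stopifnot_same_binning(map_a$binning, map_b$binning)
  mp_a <- mappable_matrix(map_a)
  mp_b <- mappable_matrix(map_b)
  M_a <- total_mappable_support(map_a, mp_a)
  M_b <- total_mappable_support(map_b, mp_b)
  if (M_a == 0 || M_b == 0) stop("a map has no mappable contacts")

  sel <- if (mappable == "both") mp_a & mp_b else mp_a | mp_b
  sel <- sel & upper.tri(sel, diag = TRUE)
  idx <- which(sel, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("no contacts mappable in both datasets")

  m_a <- ifelse(mp_a[idx], map_a$counts[idx], 0)
  m_b <- ifelse(mp_b[idx], map_b$counts[idx], 0)
  P_a <- m_a / M_a
  P_b <- m_b / M_b
  gated <- normal_approx_ok(M_a, P_a) & normal_approx_ok(M_b, P_b)

  z <- rep(NA_real_, nrow(idx)); p <- rep(NA_real_, nrow(idx))
  if (any(gated)) {
    zt <- two_proportion_pvalue(P_a[gated], M_a, P_b[gated], M_b,
                                as_printed = as_printed)
    z[gated] <- zt$z
    p[gated] <- zt$p
  }
  n_tests <- sum(gated)
  q <- rep(NA_real_, nrow(idx))
  q[gated] <- bonferroni(p[gated], n_tests)
  ratio <- pmax(P_a, P_b) / pmin(P_a, P_b)

  tab <- data.frame(i = idx[, 1] - 1L, j = idx[, 2] - 1L,
                    P_a = P_a, P_b = P_b, M_a = M_a, M_b = M_b,
                    z = z, p = p, q = q, ratio = ratio,
                    class = "untestable", stringsAsFactors = FALSE)
  tab <- classify_contacts(tab, q_threshold = q_threshold, fold = fold)
  attr(tab, "n_tests") <- n_tests
  class(tab) <- c("ContactTestTable", class(tab))
  tab
}

#' Classify tested contacts by significance and fold change
#'
#' A gated contact is `significant` when `q < q_threshold`, and
#' `significant_2fold` when additionally the larger/smaller probability
#' ratio exceeds `fold`; otherwise `not_significant`. Ungated contacts are
#' `untestable`.
#'
#' @param table A data.frame with columns `q` and `ratio` (NA q =
#'   untestable).
#' @param q_threshold,fold Thresholds (defaults 0.05 and 2).
#' @return The table with its `class` column set and a `counts` attribute
#'   tallying the classes.
#' @export
classify_contacts <- function(table, q_threshold = 0.05, fold = 2) {
  cls <- ifelse(is.na(table$q), "untestable",
         ifelse(table$q >= q_threshold, "not_significant",
         ifelse(table$ratio > fold, "significant_2fold", "significant")))
  table$class <- cls
  attr(table, "counts") <- table(factor(cls, levels = c(
    "untestable", "not_significant", "significant", "significant_2fold")))
  table
}

#' Write a contact test table as TSV in BED-pair style coordinates
#' @param table A `ContactTestTable`.
#' @param binning The `GenomeBinning` of the tested maps.
#' @param path Output path.
#' @export
write_contact_tests <- function(table, binning, path) {
  b <- binning$bins
  out <- data.frame(
    chrom_i = b$chrom[table$i + 1L], start_i = b$start[table$i + 1L],
    end_i = b$end[table$i + 1L],
    chrom_j = b$chrom[table$j + 1L], start_j = b$start[table$j + 1L],
    end_j = b$end[table$j + 1L],
    table[, c("P_a", "P_b", "z", "p", "q", "ratio", "class")]
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
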