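#' Specify a synthetic pair of Hi-C contact maps
#'
#' Describes a stylized two-cell-type Hi-C experiment with known ground
#' truth: a multi-chromosome genome, power-law distance decay of
#' intrachromosomal contacts (exponent per cell type), an alternating-block
#' plaid compartment structure entering multiplicatively as
#' `1 + e_i * e_j`, optional TAD-like enriched blocks, a uniform
#' interchromosomal background carrying a fixed fraction of the total
#' contact mass, and planted multiplicative cell-type-specific differences.
#'
#' Expectations for the two cell types are depth-normalized on the
#' *unplanted* base model, so a planted fold factor is exactly the ratio of
#' expectations between cell types at the affected pairs.
#'
#' @param chrom_bins Integer vector: number of bins per chromosome (names
#'   optional; defaults chr1, chr2, ...).
#' @param bin_size Bin width in bp (default 1e6, the 1 Mb analysis scale).
#' @param alpha Distance-decay exponents, named vector for cell types
#'   `c(a = ..., b = ...)`; a single unnamed value is used for both.
#' @param compartment `list(block_len =, amplitude =)`: alternating blocks of
#'   `block_len` bins with per-bin signed amplitude `e_i = +/- amplitude`
#'   (restarting positive at each chromosome start), or a full per-bin
#'   numeric profile. `abs(e) < 1` so the plaid factor stays positive.
#' @param tads Optional list, one element per chromosome, each
#'   `list(boundaries =, enrichment =)` where `boundaries` are 1-based bin
#'   offsets within the chromosome starting a new domain; pairs within the
#'   same domain are multiplied by `enrichment`.
#' @param trans_weight Fraction of total expected contact mass that is
#'   interchromosomal (default 0.1; real maps put >90% of contacts in cis).
#' @param coverage_bias Optional per-bin visibility multipliers emulating
#'   mappability/coverage bias, entering expectations as `b_i * b_j` (both
#'   cis and trans) before depth normalization; either a full per-bin
#'   numeric vector or `list(bins =, level =)` setting the named bins to
#'   `level` and all others to 1. Identical in both cell types. These are
#'   the bins the split-half poor-bin filter is meant to catch.
#' @param planted List of planted differences, each
#'   `list(bins =, partner = "all" or bin vector, fold =, cell =)` with
#'   1-based genome-wide bin indices; each affected unordered pair is
#'   multiplied once by `fold` in that cell type's expectation.
#' @param depth Total expected read pairs (sum of the full expectation
#'   matrix, diagonal once and off-diagonals twice).
#' @param seed Master seed; all sampling derives child seeds from it.
#' @return An object of class `SyntheticSpec`.
#' @export
synthetic_spec <- function(chrom_bins, bin_size = 1e6,
                           alpha = c(a = 1.0, b = 1.0),
                           compartment = list(block_len = 20, amplitude = 0),
                           tads = NULL, trans_weight = 0.1,
                           coverage_bias = NULL,
                           planted = list(), depth = 1e6, seed = 1L) {
  chrom_bins <- as.integer(chrom_bins)
  if (any(chrom_bins < 1)) stop("each chromosome needs at least one bin")
  if (is.null(names(chrom_bins))) {
    names(chrom_bins) <- paste0("chr", seq_along(chrom_bins))
  }
  if (is.null(names(alpha))) {
    alpha <- c(a = unname(alpha[1]), b = unname(alpha[length(alpha)]))
  }
  if (any(alpha <= 0)) stop("decay exponents must be positive")
  if (!is.finite(depth) || depth <= 0) stop("depth must be positive")
  if (trans_weight < 0 || trans_weight >= 1) stop("trans_weight must be in [0, 1)")

  binning <- genome_binning(chrom_bins * bin_size, bin_size)
  n <- binning$n_bins

  if (is.numeric(compartment) && length(compartment) == n) {
    e <- as.numeric(compartment)
  } else {
    bl <- compartment$block_len
    amp <- compartment$amplitude
    if (!is.finite(amp)) stop("compartment amplitude must be finite")
    e <- unlist(lapply(chrom_bins, function(nb) {
      blocks <- ceiling(seq_len(nb) / bl)
      amp * ifelse(blocks %% 2 == 1, 1, -1)
    }), use.names = FALSE)
  }
  if (any(abs(e) >= 1)) stop("compartment amplitudes must satisfy |e| < 1")

  if (is.null(coverage_bias)) {
    cb <- rep(1, n)
  } else if (is.numeric(coverage_bias)) {
    if (length(coverage_bias) != n) stop("coverage_bias must have one value per bin")
    cb <- as.numeric(coverage_bias)
  } else {
    if (any(coverage_bias$bins < 1 | coverage_bias$bins > n)) {
      stop("coverage_bias bins outside the genome")
    }
    cb <- rep(1, n)
    cb[coverage_bias$bins] <- coverage_bias$level
  }
  if (any(cb <= 0)) stop("coverage_bias multipliers must be positive")

  for (p in planted) {
    if (is.null(p$fold) || p$fold <= 0) stop("planted fold factors must be positive")
    if (any(p$bins < 1 | p$bins > n)) stop("planted bins outside the genome")
    if (!identical(p$partner, "all") && any(p$partner < 1 | p$partner > n)) {
      stop("planted partner bins outside the genome")
    }
    if (!p$cell %in% names(alpha)) stop("planted cell type must name an alpha entry")
  }

  if (length(tads) == 0) tads <- NULL
  obj <- list(chrom_bins = chrom_bins, bin_size = bin_size, alpha = alpha,
              compartment_profile = e, tads = tads,
              trans_weight = trans_weight, coverage_bias = cb,
              planted = planted,
              depth = depth, seed = as.integer(seed), binning = binning)
  class(obj) <- "SyntheticSpec"
  obj
}

#' @export
print.SyntheticSpec <- function(x, ...) {
  cat(sprintf(
    "SyntheticSpec: %d chromosomes / %d bins, depth %.3g, alpha (%s), %d planted difference(s)\n",
    length(x$chrom_bins), x$binning$n_bins, x$depth,
    paste(sprintf("%s=%.3g", names(x$alpha), x$alpha), collapse = ", "),
    length(x$planted)))
  invisible(x)
}

# base (unplanted) expectation matrix for one cell type, summing to depth
base_expectation <- function(spec, cell_type) {
  n <- spec$binning$n_bins
  a <- spec$alpha[[cell_type]]
  e <- spec$compartment_profile
  E <- matrix(0, n, n)
  offset <- 0L
  for (ci in seq_along(spec$chrom_bins)) {
    nb <- spec$chrom_bins[[ci]]
    idx <- offset + seq_len(nb)
    d <- abs(outer(seq_len(nb), seq_len(nb), "-"))
    w <- ifelse(d == 0, 0, d^(-a))
    w <- w * (1 + outer(e[idx], e[idx]))
    if (!is.null(spec$tads) && length(spec$tads) >= ci &&
        !is.null(spec$tads[[ci]])) {
      td <- spec$tads[[ci]]
      dom <- findInterval(seq_len(nb), sort(unique(c(1L, td$boundaries))))
      w <- w * ifelse(outer(dom, dom, "==") & d > 0, td$enrichment, 1)
    }
    E[idx, idx] <- w
    offset <- offset + nb
  }
  trans <- outer(spec$binning$bin_chrom, spec$binning$bin_chrom, "!=")
  E[trans] <- 1
  cbm <- outer(spec$coverage_bias, spec$coverage_bias)
  E <- E * cbm
  cis_sum <- sum(E[!trans])
  trans_sum <- sum(E[trans])
  w_t <- spec$trans_weight
  Eout <- E
  if (cis_sum > 0) Eout[!trans] <- E[!trans] * ((1 - w_t) * spec$depth / cis_sum)
  if (trans_sum > 0 && w_t > 0) {
    Eout[trans] <- E[trans] * (w_t * spec$depth / trans_sum)
  } else {
    Eout[trans] <- 0
  }
  Eout
}

apply_planted <- function(E, spec, cell_type) {
  n <- nrow(E)
  for (p in spec$planted) {
    if (p$cell != cell_type) next
    partner <- if (identical(p$partner, "all")) seq_len(n) else p$partner
    f <- matrix(1, n, n)
    f[p$bins, partner] <- p$fold
    f[partner, p$bins] <- p$fold
    E <- E * f
  }
  E
}

#' Expectation matrix of a synthetic spec for one cell type
#'
#' @param spec A `SyntheticSpec`.
#' @param cell_type Cell-type label naming an `alpha` entry (e.g. `"a"`).
#' @return Symmetric matrix of expected counts. Without planted differences
#'   its full sum equals the spec depth; planted factors change mass at the
#'   affected pairs only.
#' @export
expectation_matrix <- function(spec, cell_type = "a") {
  apply_planted(base_expectation(spec, cell_type), spec, cell_type)
}

#' Expected count at a single bin pair
#'
#' @param spec A `SyntheticSpec`.
#' @param cell_type Cell-type label.
#' @param i,j 1-based genome-wide bin indices.
#' @return The deterministic expectation at `(i, j)`.
#' @export
expected_count <- function(spec, cell_type, i, j) {
  n <- spec$binning$n_bins
  if (any(c(i, j) < 1) || any(c(i, j) > n)) stop("bin index out of range")
  E <- expectation_matrix(spec, cell_type)
  E[cbind(i, j)]
}

# deterministic child seed: master seed plus a hash of the cell type's own
# parameters, so identical per-type parameters reproduce identical draws
child_seed <- function(spec, cell_type) {
  own <- spec$planted[vapply(spec$planted, function(p) p$cell == cell_type, TRUE)]
  key <- paste(format(spec$alpha[[cell_type]], digits = 15),
               paste(vapply(own, function(p) {
                 paste(c(p$bins, p$partner, format(p$fold, digits = 15)),
                       collapse = "_")
               }, ""), collapse = "|"))
  h <- sum(utf8ToInt(key) * seq_along(utf8ToInt(key))) %% 100003L
  (spec$seed + h) %% .Machine$integer.max
}

sample_poisson_map <- function(spec, E, seed) {
  n <- nrow(E)
  set.seed(seed)
  ut <- upper.tri(E, diag = TRUE)
  x <- matrix(0, n, n)
  x[ut] <- stats::rpois(sum(ut), E[ut])
  x <- x + t(x) - diag(diag(x))
  contact_map(spec$binning, x)
}

#' Generate a synthetic contact-map pair with ground truth
#'
#' Draws independent Poisson counts around each cell type's expectation
#' matrix (upper triangle sampled, then symmetrized). The master seed fully
#' determines the output; each cell type's child seed depends only on the
#' master seed and on that cell type's own parameters, so two cell types
#' with identical parameters yield identical maps.
#'
#' @param spec A `SyntheticSpec`.
#' @return List with raw `ContactMap`s `map_a`, `map_b` and `truth` (planted
#'   differences, exponents, compartment profile, seed).
#' @export
generate_pair <- function(spec) {
  types <- names(spec$alpha)[1:2]
  maps <- lapply(types, function(ct) {
    sample_poisson_map(spec, expectation_matrix(spec, ct), child_seed(spec, ct))
  })
  list(
    map_a = maps[[1]], map_b = maps[[2]],
    truth = list(planted = spec$planted, alpha = spec$alpha,
                 compartment_profile = spec$compartment_profile,
                 trans_weight = spec$trans_weight, depth = spec$depth,
                 seed = spec$seed)
  )
}

#' Sample one map from a spec with an explicit seed
#'
#' Used to draw independent replicates of the same expectation (e.g. for
#' null calibration of the contact test).
#'
#' @param spec A `SyntheticSpec`.
#' @param cell_type Cell-type label.
#' @param seed RNG seed for this draw.
#' @return A raw `ContactMap`.
#' @export
sample_map <- function(spec, cell_type = "a", seed = spec$seed) {
  sample_poisson_map(spec, expectation_matrix(spec, cell_type), seed)
}

#' Sample a deep, plant-free reference map from a spec
#'
#' Draws an independent Poisson map from the *unplanted* base expectation of
#' one cell type, at a multiple of the spec's depth. This plays the role of
#' the deep independent reference library whose split halves calibrate the
#' poor-bin filter and the bias-exclusion rankings: at higher depth the
#' split-half correlation noise of well-covered bins shrinks, so the
#' `C_i < M - SD` rule converges onto the genuinely low-visibility bins
#' instead of clipping the noise bulk.
#'
#' @param spec A `SyntheticSpec`.
#' @param cell_type Cell type whose base parameters to use.
#' @param depth_factor Reference depth as a multiple of `spec$depth`
#'   (default 4).
#' @param seed RNG seed (default derived from the spec's master seed).
#' @return A raw `ContactMap`.
#' @export
sample_reference_map <- function(spec, cell_type = "a", depth_factor = 4,
                                 seed = (spec$seed + 777L) %% .Machine$integer.max) {
  E <- base_expectation(spec, cell_type) * depth_factor
  sample_poisson_map(spec, E, seed)
}

#' Split a raw map into two half-depth replicates by binomial thinning
#'
#' Each read of every contact is assigned to one half with probability 1/2;
#' the two halves sum to the input exactly. This reproduces the
#' split-half "reference" construction used to flag regionally biased bins.
#'
#' @param map A raw `ContactMap` with integer counts.
#' @param seed RNG seed.
#' @return List of two raw `ContactMap`s.
#' @export
thin_split <- function(map, seed = 1L) {
  if (map$value_kind != "raw") stop("thin_split needs raw counts")
  n <- nrow(map$counts)
  set.seed(seed)
  ut <- upper.tri(map$counts, diag = TRUE)
  h1 <- matrix(0, n, n)
  h1[ut] <- stats::rbinom(sum(ut), size = as.integer(round(map$counts[ut])),
                          prob = 0.5)
  h1 <- h1 + t(h1) - diag(diag(h1))
  h2 <- map$counts - h1
  list(contact_map(map$binning, h1, masked = map$masked),
       contact_map(map$binning, h2, masked = map$masked))
}
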