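test_that("per-bin Euclidean distance matches hand arithmetic and vanishes on equality", {
  x <- matrix(0, 3, 3)
  x[1, 2] <- x[2, 1] <- 2; x[1, 3] <- x[3, 1] <- 3; x[2, 3] <- x[3, 2] <- 1
  y <- matrix(0, 3, 3)
  y[1, 2] <- y[2, 1] <- 4; y[1, 3] <- y[3, 1] <- 1; y[2, 3] <- y[3, 2] <- 1
  e <- bin_euclidean_profile(tiny_map(x), tiny_map(y))
  expect_equal(e[1], sqrt((2 - 4)^2 + (3 - 1)^2))  # sqrt(8)
  m <- random_symmetric_map(10, seed = 1)
  expect_true(all(bin_euclidean_profile(m, m) == 0))
})

test_that("per-bin profiles match exhaustive brute-force oracles", {
  a <- random_symmetric_map(50, lambda = 12, seed = 31, chrom_bins = c(30, 20))
  b <- random_symmetric_map(50, lambda = 12, seed = 32, chrom_bins = c(30, 20))
  chrom_of <- a$binning$bin_chrom

  expect_equal(bin_euclidean_profile(a, b),
               oracle_euclid(a$counts, b$counts, chrom_of), tolerance = 1e-9)

  co <- bin_correlation_profile(a, b)
  expect_equal(co$pearson, oracle_bin_cor(a$counts, b$counts, chrom_of),
               tolerance = 1e-9)
  expect_equal(co$spearman,
               oracle_bin_cor(a$counts, b$counts, chrom_of, "spearman"),
               tolerance = 1e-9)
})

test_that("per-bin correlations hit the documented extremes", {
  base <- matrix(0, 4, 4)
  x <- base; x[1, 2:4] <- c(1, 2, 3); x[2:4, 1] <- c(1, 2, 3)
  y <- base; y[1, 2:4] <- c(3, 2, 1); y[2:4, 1] <- c(3, 2, 1)
  co <- bin_correlation_profile(tiny_map(x), tiny_map(y))
  expect_equal(co$pearson[1], -1)

  m <- random_symmetric_map(6, lambda = 40, seed = 2)
  self <- bin_correlation_profile(m, m)
  expect_equal(self$pearson, rep(1, 6))
})

test_that("metrics are symmetric under exchanging the maps", {
  a <- random_symmetric_map(24, lambda = 15, seed = 41, chrom_bins = c(12, 12))
  b <- random_symmetric_map(24, lambda = 15, seed = 42, chrom_bins = c(12, 12))
  expect_equal(bin_euclidean_profile(a, b), bin_euclidean_profile(b, a))
  expect_equal(bin_correlation_profile(a, b)$pearson,
               bin_correlation_profile(b, a)$pearson)
})

test_that("poor-bin filter reproduces the hand-computed threshold case", {
  binning <- tiny_binning(5)
  c_i <- c(0.9, 0.9, 0.9, 0.9, 0.1)
  fl <- poor_bin_filter(c_i, binning)
  # M = 0.9, SD = 0.35777; threshold ~0.5422
  expect_equal(stats::sd(c_i), 0.3577709, tolerance = 1e-6)
  expect_identical(which(fl$poor), 5L)
  expect_identical(which(fl$flank), 4L)

  none <- poor_bin_filter(rep(0.8, 6), tiny_binning(6))
  expect_false(any(none$poor) || any(none$flank))
})

test_that("flanks stop at chromosome boundaries", {
  binning <- tiny_binning(c(3, 3))
  c_i <- c(0.9, 0.9, 0.9, 0.1, 0.9, 0.9)  # poor bin = first bin of chr2
  fl <- poor_bin_filter(c_i, binning)
  expect_identical(which(fl$poor), 4L)
  expect_identical(which(fl$flank), 5L)  # bin 3 is on chr1: not a flank
})

test_that("expected overlap follows the counting formula", {
  expect_equal(expected_overlap(100, 100, 100, 2308), 1e6 / 2308^2)
  expect_equal(expected_overlap(100, 100, 100, 2308), 0.18773, tolerance = 1e-4)
  expect_equal(expected_overlap(7, 7, 7, 7), 7)
  expect_equal(expected_overlap(0, 100, 100, 2308), 0)
  expect_error(expected_overlap(1, 1, 1, 0), "positive")
  expect_error(expected_overlap(10, 1, 1, 5), "exceed")
})

test_that("ranks are a permutation over non-excluded bins and selection degenerates correctly", {
  a <- random_symmetric_map(30, lambda = 25, seed = 51, chrom_bins = c(15, 15))
  b <- random_symmetric_map(30, lambda = 25, seed = 52, chrom_bins = c(15, 15))
  tab <- bin_difference_table(a, b)
  for (rc in c("rank_euclid", "rank_pearson", "rank_eigen")) {
    r <- tab[[rc]][!is.na(tab[[rc]])]
    expect_setequal(r, seq_along(r))
  }
  cand <- select_candidates(tab, NULL, n = sum(!tab$excluded))
  expect_setequal(cand$intersection, which(!is.na(tab$rank_euclid)))
  expect_error(select_candidates(tab, NULL, n = 1e4), "exceeds")
})

test_that("null comparisons produce no more overlap than chance allows", {
  # thinned halves of one map in the full-scale world; in small homogeneous
  # worlds the three metrics share sampling noise and the bound is not tight
  sp <- preset_spec("regional", seed = 31)
  sp$planted <- list()
  m <- sample_map(sp, "a", seed = 531)
  halves <- thin_split(m, seed = 31)
  cp <- corrected_pair(list(map_a = halves[[1]], map_b = halves[[2]]),
                       mask_percentile = 0.05)
  refmap <- sample_reference_map(sp)
  ref <- reference_difference_table(refmap, seed = 31)
  tab <- bin_difference_table(cp$a, cp$b, reference_c = ref$c_i)
  cand <- select_candidates(tab, ref$table, n = 100)
  expect_lte(length(cand$intersection), cand$expected + 3)
})

test_that("planted-region recovery improves with the planted fold", {
  set.seed(55)
  cb <- exp(rnorm(500, 0, 0.35))
  cb[105:115] <- 1  # planted stretch in average-visibility terrain
  recovered <- vapply(c(2, 5, 10), function(fold) {
    # region of block 6 (B sign) rewired toward two A-sign blocks
    sp <- synthetic_spec(rep(250L, 2), alpha = c(a = 1, b = 1),
                         compartment = list(block_len = 20, amplitude = 0.6),
                         trans_weight = 0.1, depth = 3e6, seed = 17,
                         coverage_bias = cb,
                         planted = list(list(
                           bins = 108:112,
                           partner = c(161:180, 201:220), fold = fold,
                           cell = "b")))
    pr <- generate_pair(sp)
    cp <- corrected_pair(pr, mask_percentile = 0.05)
    refmap <- sample_reference_map(sp)
    ref <- reference_difference_table(refmap, seed = 17)
    tab <- bin_difference_table(cp$a, cp$b, reference_c = ref$c_i)
    # candidate sets sized proportionally to the 100-of-2308 analysis scale
    cand <- select_candidates(tab, ref$table, n = 25)
    sum(sp$planted[[1]]$bins %in% cand$intersection)
  }, numeric(1))
  expect_true(all(diff(recovered) >= 0))
  expect_gt(recovered[3], recovered[1])
  # lottery losses from the reference rank exclusion allow <= 2 misses
  expect_gte(recovered[3], 3)
})
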