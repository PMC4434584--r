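noiseless_map <- function(alpha, chrom_bins = c(60L, 40L), depth = 1e6,
                          trans_weight = 0.1) {
  sp <- synthetic_spec(chrom_bins, alpha = c(a = alpha, b = alpha),
                       compartment = list(block_len = 10, amplitude = 0),
                       trans_weight = trans_weight, depth = depth, seed = 1)
  contact_map(sp$binning, expectation_matrix(sp, "a"))
}

test_that("P(s) reproduces the construction on a noiseless power-law map", {
  m <- noiseless_map(1.4)
  cv <- ps_curve(m)
  pred <- cv$prob[1] * (cv$distance / cv$distance[1])^(-1.4)
  expect_equal(cv$prob, pred, tolerance = 1e-9)

  m2 <- m; m2$counts <- m$counts * 3.5; m2$total <- sum(m2$counts)
  cv2 <- ps_curve(m2)
  expect_equal(cv2$prob, cv$prob * 3.5, tolerance = 1e-12)
})

test_that("a single-separation map yields a single nonzero curve point", {
  x <- matrix(0, 6, 6)
  for (i in 1:5) x[i, i + 1] <- x[i + 1, i] <- 2
  cv <- ps_curve(tiny_map(x))
  expect_equal(cv$prob[cv$distance == 1e6], 2)
  expect_true(all(cv$prob[cv$distance > 1e6] == 0))
})

test_that("power-law fits are exact on noiseless curves across exponents", {
  for (a in c(0.5, 0.9, 1.27, 2)) {
    cv <- ps_curve(noiseless_map(a))
    f <- fit_power_law(cv, fit_range = range(cv$distance))
    expect_equal(f$exponent, -a, tolerance = 1e-9)
    expect_lt(f$se, 1e-8)
  }
  expect_error(fit_power_law(data.frame(distance = c(1, 2), prob = c(1, 0.5),
                                        n_pairs = c(10, 10)),
                             fit_range = c(1, 2)), "fewer than 3")
})

test_that("curve ratios behave algebraically", {
  ca <- ps_curve(noiseless_map(1.07))
  cb <- ps_curve(noiseless_map(1.27))
  r <- ps_ratio(ca, cb)
  fit <- stats::lm(log10(ratio) ~ log10(distance), data = r)
  expect_equal(unname(stats::coef(fit)[2]), 0.2, tolerance = 1e-9)

  expect_true(all(ps_ratio(ca, ca)$ratio == 1))
  cz <- cb; cz$prob[3] <- 0
  expect_true(is.na(ps_ratio(ca, cz)$ratio[3]))
})

test_that("cis/trans ratios count intra and inter contacts as documented", {
  x <- matrix(0, 4, 4)
  x[1, 2] <- x[2, 1] <- 45        # chr1 intra total 90
  x[3, 4] <- x[4, 3] <- 45        # chr2 intra total 90
  x[1, 3] <- x[3, 1] <- 10        # 10 per direction
  m <- contact_map(tiny_binning(c(2, 2)), x)
  ct <- cis_trans_ratio(m)
  expect_equal(ct$per_chromosome$ratio, c(9, 9))
  expect_equal(ct$genome_wide, 9)

  bd <- matrix(0, 4, 4); bd[1, 2] <- bd[2, 1] <- 5; bd[3, 4] <- bd[4, 3] <- 5
  expect_warning(ctbd <- cis_trans_ratio(contact_map(tiny_binning(c(2, 2)), bd)),
                 "zero trans")
  expect_true(all(is.infinite(ctbd$per_chromosome$ratio)))
})

test_that("genome-wide cis/trans matches the generator's trans weight", {
  sp <- synthetic_spec(c(80L, 80L), alpha = c(a = 1, b = 1),
                       compartment = list(block_len = 10, amplitude = 0),
                       trans_weight = 0.25, depth = 2e6, seed = 9)
  m <- sample_map(sp, "a", seed = 9)
  ct <- cis_trans_ratio(m)
  expect_equal(ct$genome_wide, 0.75 / 0.25, tolerance = 0.05)
})

test_that("interchromosomal enrichment reproduces the worked example", {
  x <- matrix(0, 3, 3)
  x[1, 2] <- x[2, 1] <- 10
  x[1, 3] <- x[3, 1] <- 20
  x[2, 3] <- x[3, 2] <- 30
  m <- contact_map(tiny_binning(c(1, 1, 1)), x)
  ic <- interchrom_enrichment(m)
  expect_equal(unname(ic$S), c(30, 40, 50))
  expect_equal(ic$T, 60)
  expect_equal(ic$expected[1, 2],
               oracle_interchrom_expected(c(30, 40, 50), 60, 1, 2))
  expect_equal(ic$expected[1, 2], 50)
  expect_equal(ic$enrichment[1, 2], 0.2)

  ic2 <- interchrom_enrichment(m, as_printed = TRUE)
  expect_equal(ic2$expected[1, 2], 40)  # (T - S_i) repeated, as printed

  md <- m; md$counts <- m$counts * 2; md$raw <- md$counts; md$total <- sum(md$counts)
  expect_equal(interchrom_enrichment(md)$enrichment, ic$enrichment)
})

test_that("uniform trans worlds give near-unit enrichment everywhere", {
  sp <- synthetic_spec(rep(40L, 4), alpha = c(a = 1, b = 1),
                       compartment = list(block_len = 10, amplitude = 0),
                       trans_weight = 0.4, depth = 5e6, seed = 12)
  m <- sample_map(sp, "a", seed = 12)
  ic <- interchrom_enrichment(m)
  en <- ic$enrichment[upper.tri(ic$enrichment)]
  # the published expectation formula is not normalized to 1 under a uniform
  # background (equal chromosomes give a common constant < 1); the null
  # content of the check is flatness across chromosome pairs
  expect_lt(max(en) / min(en), 1.1 / 0.9)
  expect_lt(stats::sd(en) / mean(en), 0.02)
})

test_that("length-difference correlation matches the base oracle and is label invariant", {
  sizes <- c(chrA = 5e6, chrB = 3e6, chrC = 8e6, chrD = 1e6)
  binning <- genome_binning(sizes, 1e6)
  nc <- 4
  len <- binning$chromosomes$length
  dl <- abs(outer(len, len, "-"))
  enr <- 2 - dl / max(dl)           # decreasing in |dL|
  obs <- enr                         # stand-in observed == enrichment
  ic <- list(enrichment = enr, observed = obs)
  class(ic) <- "InterchromMatrix"
  r <- length_diff_correlation(ic, binning)
  ut <- upper.tri(enr)
  expect_equal(r, stats::cor(enr[ut], dl[ut]))
  expect_lt(r, 0)

  flat <- ic; flat$enrichment[] <- 1
  expect_error(length_diff_correlation(flat, binning), "constant")

  perm <- c(3, 1, 4, 2)
  binning_p <- genome_binning(sizes[perm], 1e6)
  ic_p <- list(enrichment = enr[perm, perm], observed = obs[perm, perm])
  class(ic_p) <- "InterchromMatrix"
  expect_equal(length_diff_correlation(ic_p, binning_p), r, tolerance = 1e-9)
})
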