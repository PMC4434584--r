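spec_plain <- function(seed = 1, ...) {
  synthetic_spec(c(6L, 4L), bin_size = 1e6, alpha = c(a = 1.2, b = 1.2),
                 compartment = list(block_len = 2, amplitude = 0),
                 trans_weight = 0.2, depth = 1e4, seed = seed, ...)
}

test_that("expected counts follow the configured power-law decay", {
  sp <- spec_plain()
  r <- expected_count(sp, "a", 1, 3) / expected_count(sp, "a", 1, 2)
  expect_equal(r, 2^(-1.2), tolerance = 1e-12)
  r4 <- expected_count(sp, "a", 1, 5) / expected_count(sp, "a", 1, 3)
  expect_equal(r4, 2^(-1.2), tolerance = 1e-12)
})

test_that("planted folds are exact expectation ratios between cell types", {
  sp <- synthetic_spec(c(6L, 4L), alpha = c(a = 1, b = 1),
                       compartment = list(block_len = 2, amplitude = 0.4),
                       trans_weight = 0.2, depth = 1e4, seed = 1,
                       planted = list(list(bins = 2:3, partner = "all",
                                           fold = 3, cell = "b")))
  Ea <- expectation_matrix(sp, "a")
  Eb <- expectation_matrix(sp, "b")
  expect_equal(Eb[2, 5] / Ea[2, 5], 3, tolerance = 1e-12)
  expect_equal(Eb[3, 8] / Ea[3, 8], 3, tolerance = 1e-12)  # trans pair too
  expect_equal(Eb[2, 3] / Ea[2, 3], 3, tolerance = 1e-12)  # within the set: once
  expect_equal(Eb[5, 6] / Ea[5, 6], 1, tolerance = 1e-12)  # untouched pair
})

test_that("unplanted expectation matrices sum to the requested depth", {
  for (s in 1:3) {
    sp <- synthetic_spec(c(5L, 7L, 3L), alpha = c(a = 0.8 + 0.2 * s, b = 1),
                         compartment = list(block_len = 3, amplitude = 0.5),
                         trans_weight = 0.15, depth = 10^(3 + s), seed = s)
    E <- expectation_matrix(sp, "a")
    expect_equal(sum(E), sp$depth, tolerance = 1e-9)
    expect_equal(E, t(E))
    expect_true(all(E >= 0))
  }
})

test_that("coverage bias enters expectations as a product of bin visibilities", {
  cb <- rep(1, 10); cb[2] <- 0.25
  sp <- spec_plain(coverage_bias = cb)
  sp0 <- spec_plain()
  E <- expectation_matrix(sp, "a")
  # same-separation pairs: visibility ratio survives depth normalization
  expect_equal(E[2, 4] / E[1, 3], 0.25, tolerance = 1e-9)
  expect_equal(E[2, 8] / E[3, 8], 0.25, tolerance = 1e-9)  # trans
  expect_equal(sum(E), spec_plain()$depth, tolerance = 1e-9)
})

test_that("generation is deterministic and parameter-tied", {
  sp <- preset_spec("calibration", seed = 5)
  p1 <- generate_pair(sp)
  p2 <- generate_pair(sp)
  expect_identical(p1$map_a$counts, p2$map_a$counts)
  expect_identical(p1$map_b$counts, p2$map_b$counts)
  # identical per-type parameters with one master seed: identical maps
  expect_identical(p1$map_a$counts, p1$map_b$counts)
  # different exponents: different draws
  sp2 <- preset_spec("compression", seed = 5)
  p3 <- generate_pair(sp2)
  expect_false(identical(p3$map_a$counts, p3$map_b$counts))
})

test_that("replicate draws average to the expectation", {
  sp <- spec_plain(seed = 2)
  E <- expectation_matrix(sp, "a")
  i <- 1; j <- 2
  draws <- vapply(seq_len(200), function(k) {
    sample_map(sp, "a", seed = 1000 + k)$counts[i, j]
  }, numeric(1))
  se <- sqrt(E[i, j] / 200)
  expect_lt(abs(mean(draws) - E[i, j]), 3 * se + 1e-9)
})

test_that("sampled maps converge to the expectation with depth", {
  rel_err <- vapply(c(1e4, 1e6), function(d) {
    sp <- synthetic_spec(c(8L, 8L), alpha = c(a = 1, b = 1),
                         compartment = list(block_len = 4, amplitude = 0.5),
                         trans_weight = 0.1, depth = d, seed = 3)
    E <- expectation_matrix(sp, "a")
    m <- sample_map(sp, "a", seed = 42)
    mean(abs(m$counts - E)) / mean(E)
  }, numeric(1))
  expect_lt(rel_err[2], rel_err[1] / 3)
})

test_that("compartment sign pattern is a checkerboard at block resolution", {
  sp <- synthetic_spec(c(8L), alpha = c(a = 1, b = 1),
                       compartment = list(block_len = 2, amplitude = 0.5),
                       trans_weight = 0, depth = 1e4, seed = 1)
  e <- sp$compartment_profile
  expect_equal(sign(e), rep(c(1, 1, -1, -1), 2))
  S <- sign(outer(e, e))
  blocks <- ceiling(seq_len(8) / 2)
  expect_true(all(S == outer(blocks, blocks,
                             function(a, b) ifelse((a + b) %% 2 == 0, 1, -1))))
})

test_that("thin_split conserves counts exactly and halves deep entries fairly", {
  m <- random_symmetric_map(10, lambda = 9, seed = 6)
  h <- thin_split(m, seed = 4)
  expect_equal(h[[1]]$counts + h[[2]]$counts, m$counts,
               ignore_attr = TRUE, tolerance = 0)

  z <- thin_split(tiny_map(matrix(0, 4, 4)), seed = 1)
  expect_true(all(z[[1]]$counts == 0) && all(z[[2]]$counts == 0))

  big <- matrix(0, 2, 2); big[1, 2] <- big[2, 1] <- 1e6
  hb <- thin_split(tiny_map(big), seed = 9)
  expect_lt(abs(hb[[1]]$counts[1, 2] - 5e5), 3 * sqrt(2.5e5))
})

test_that("spec validation rejects impossible worlds", {
  expect_error(synthetic_spec(c(5L), alpha = c(a = -1, b = 1)), "positive")
  expect_error(synthetic_spec(c(5L), depth = 0), "depth")
  expect_error(synthetic_spec(c(5L),
                              compartment = list(block_len = 2, amplitude = 1.2)),
               "< 1")
  expect_error(synthetic_spec(c(5L),
                              planted = list(list(bins = 9, partner = "all",
                                                  fold = 2, cell = "a"))),
               "outside")
  expect_error(synthetic_spec(c(5L),
                              planted = list(list(bins = 1, partner = "all",
                                                  fold = -2, cell = "a"))),
               "positive")
})
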