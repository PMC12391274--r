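test_that("COO round trip preserves bins, pixels and weights", {
  m <- uniform_matrix(12)
  m$weights <- runif(12, 0.5, 2)
  prefix <- file.path(tempdir(), "rt")
  write_matrix(m, prefix)
  m2 <- read_matrix(prefix)
  expect_equal(m2$bins, m$bins)
  expect_equal(m2$pixels, m$pixels)
  expect_equal(m2$weights, m$weights, tolerance = 1e-12)
})

test_that("lower-triangular triplets are normalised and duplicates summed", {
  bins <- data.frame(chrom = "chr1", start = c(0, 1e5, 2e5),
                     end = c(1e5, 2e5, 3e5))
  px <- data.frame(bin1 = c(3, 1, 1), bin2 = c(1, 3, 2), count = c(4, 6, 2))
  m <- contact_matrix(bins, px, resolution = 1e5)
  expect_true(all(m$pixels$bin1 <= m$pixels$bin2))
  expect_equal(m$pixels$count[m$pixels$bin1 == 1 & m$pixels$bin2 == 3], 10)
})

test_that("invalid bin tables and counts are rejected", {
  bins_gap <- data.frame(chrom = "chr1", start = c(0, 2e5), end = c(1e5, 3e5))
  px <- data.frame(bin1 = 1, bin2 = 2, count = 1)
  expect_error(contact_matrix(bins_gap, px, resolution = 1e5), "gaps")
  bins <- data.frame(chrom = "chr1", start = c(0, 1e5), end = c(1e5, 2e5))
  expect_error(contact_matrix(bins, data.frame(bin1 = 1, bin2 = 2, count = -1),
                              resolution = 1e5), "negative")
  expect_error(contact_matrix(bins, data.frame(bin1 = 1, bin2 = 5, count = 1),
                              resolution = 1e5), "outside")
})

test_that("marginals equal the brute-force both-mates sum", {
  set.seed(3)
  n <- 8
  counts <- matrix(rpois(n * n, 5), n, n)
  counts <- counts + t(counts)
  m <- dense_to_matrix(counts)
  # each pair contributes one end per mate; diagonal pairs contribute twice
  expected <- rowSums(counts) + diag(counts)
  expect_equal(marginals(m), expected)
})

test_that("balancing equalises marginals and finds the analytic fixed point", {
  # rank-1 toy: counts = outer(u, u); iterative correction weights ~ 1/u
  u <- c(1, 1, 2, 1, 1)
  counts <- 40 * outer(u, u)
  m <- balance(dense_to_matrix(counts), min_nnz = 1, tol = 1e-10)
  w <- as.numeric(m$weights)
  expect_equal(w[3] / w[1], 0.5, tolerance = 1e-6)
  # constant matrix: all weights equal
  m2 <- balance(uniform_matrix(10), min_nnz = 1)
  expect_lt(diff(range(as.numeric(m2$weights))), 1e-6)
})

test_that("balancing masks empty bins and is idempotent", {
  counts <- matrix(10, 8, 8)
  counts[4, ] <- 0; counts[, 4] <- 0
  m <- balance(dense_to_matrix(counts), min_nnz = 1)
  expect_true(is.na(m$weights[4]))
  expect_true(all(!is.na(m$weights[-4])))
  m2 <- balance(m, min_nnz = 1)
  expect_equal(as.numeric(m2$weights[-4]), as.numeric(m$weights[-4]),
               tolerance = 1e-4)
})

test_that("O/E is 1 for a matrix equal to its expectation and scale invariant", {
  m <- balance(uniform_matrix(20), min_nnz = 1)
  oe <- observed_over_expected(m, "cis")
  expect_equal(oe$pixels$oe, rep(1, nrow(oe$pixels)), tolerance = 1e-6)
  m2 <- m
  m2$pixels$count <- m2$pixels$count * 2
  m2 <- balance(m2, min_nnz = 1)
  oe2 <- observed_over_expected(m2, "cis")
  expect_equal(oe2$pixels$oe, oe$pixels$oe, tolerance = 1e-6)
  expect_equal(nrow(oe$pixels), nrow(m$pixels))
})

test_that("O/E of a planted checkerboard is elevated on same-label pairs", {
  spec <- synthetic_spec(c(chr1 = 40e6), 2e5,
                         compartments = list(block_size = 4e6, strength = 0.8),
                         depth = 4e6, seed = 2)
  m <- balance(simulate_matrix(spec)$matrix)
  oe <- observed_over_expected(m, "cis")
  l <- spec$labels$chr1
  same <- l[oe$pixels$bin1] * l[oe$pixels$bin2]
  expect_gt(mean(oe$pixels$oe[same > 0]), 1)
  expect_lt(mean(oe$pixels$oe[same < 0]), 1)
})

test_that("arm labelling follows the bin-midpoint convention", {
  bins <- bin_table(c(chr1 = 10e5, chr2 = 10e5), 1e5)
  cen <- data.frame(chrom = "chr1", start = 45e4, end = 55e4)
  expect_warning(arms <- split_arms(bins, cen), "chr2")
  a1 <- arms[bins$chrom == "chr1"]
  expect_equal(sum(a1 == "chr1_p", na.rm = TRUE), 4)
  expect_equal(sum(a1 == "chr1_q", na.rm = TRUE), 5)
  expect_equal(sum(is.na(a1)), 1)  # bin straddling the centromere
  expect_true(all(arms[bins$chrom == "chr2"] == "chr2"))
  # acrocentric: centromere at the start leaves a single q arm
  cen2 <- data.frame(chrom = c("chr1", "chr2"),
                     start = c(0, 45e4), end = c(1e5, 55e4))
  arms2 <- split_arms(bins, cen2)
  expect_true(all(arms2[bins$chrom == "chr1"] == "chr1_q", na.rm = TRUE))
})
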