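make_comp_sample <- function(s, seed, size = 60e6) {
  spec <- synthetic_spec(c(chr1 = size), 1e5, depth = 8e6, seed = seed,
                         compartments = list(block_size = 4e6, strength = s))
  sim <- simulate_matrix(spec)
  list(spec = spec, m = balance(sim$matrix), gc = simulate_tracks(spec)$gc)
}

test_that("compartment score recovers planted A/B labels and GC signing holds", {
  smp <- make_comp_sample(0.8, seed = 11)
  cs <- compartment_score(smp$m, smp$gc)
  l <- smp$spec$labels$chr1
  ok <- !is.na(cs$score) & l != 0
  expect_gt(mean(sign(cs$score[ok]) == l[ok]), 0.95)
  expect_gte(cor(cs$score[ok], smp$gc[ok]), 0)
})

test_that("without compartment structure the leading eigenvector is weak", {
  smp0 <- make_comp_sample(0, seed = 12)
  smp1 <- make_comp_sample(0.8, seed = 12)
  cs0 <- compartment_score(smp0$m, smp0$gc)
  cs1 <- compartment_score(smp1$m, smp1$gc)
  expect_lt(cs0$var_share[["chr1"]], cs1$var_share[["chr1"]] / 2)
  expect_lt(mean(abs(cs0$score), na.rm = TRUE),
            mean(abs(cs1$score), na.rm = TRUE))
})

test_that("reference synchronisation leaves GC-signed scores unchanged", {
  smp <- make_comp_sample(0.8, seed = 13)
  cs <- compartment_score(smp$m, smp$gc)
  cs_ref <- compartment_score(smp$m, smp$gc, reference = cs)
  expect_equal(cs_ref$score, cs$score)
})

test_that("saddle with Q = 2 on a 4-bin arm equals hand-computed block means", {
  vals <- matrix(c(0, 4, 2, 1,
                   4, 0, 3, 2,
                   2, 3, 0, 6,
                   1, 2, 6, 0), 4, 4)
  m <- dense_to_matrix(vals, bin_size = 1e5)
  cs <- structure(list(bins = m$bins, score = c(-2, -1, 1, 2),
                       arms = m$bins$chrom, eigenvalues = c(chr1 = 1),
                       var_share = c(chr1 = 1)), class = "CompartmentScore")
  sd_ <- suppressMessages(saddle(m, cs, Q = 2))
  # O/E first: per-separation means over 4 bins
  prof <- expected_profile(m)$cis$chr1
  oe <- vals / matrix(prof[abs(outer(1:4, 1:4, "-")) + 1], 4, 4)
  # quantiles: bins 1,2 = B (q1), bins 3,4 = A (q2); off-diagonal pairs only
  expect_equal(sd_$matrix[1, 1], oe[1, 2])
  expect_equal(sd_$matrix[2, 2], oe[3, 4])
  expect_equal(sd_$matrix[1, 2], mean(c(oe[1, 3], oe[1, 4], oe[2, 3], oe[2, 4])))
  expect_equal(sd_$matrix[1, 2], sd_$matrix[2, 1])
})

test_that("saddle is flat for permuted scores and structured for planted ones", {
  smp <- make_comp_sample(0.8, seed = 14)
  cs <- compartment_score(smp$m, smp$gc)
  sd1 <- saddle(smp$m, cs, Q = 10)
  k <- 2
  expect_gt(mean(sd1$matrix[1:k, 1:k]), 1)
  expect_gt(mean(sd1$matrix[9:10, 9:10]), 1)
  expect_lt(mean(sd1$matrix[1:k, 9:10]), 1)
  expect_equal(mean(sd1$matrix, na.rm = TRUE), 1, tolerance = 0.1)
  csp <- cs
  set.seed(1)
  csp$score <- sample(cs$score)  # permuted scores break the association
  sd0 <- saddle(smp$m, csp, Q = 10)
  expect_lt(max(abs(sd0$matrix - 1), na.rm = TRUE), 0.2)
})

test_that("compartment strength is 1 for a flat saddle and bootstraps collapse on one arm", {
  Q <- 10
  flat <- structure(list(matrix = matrix(1, Q, Q),
                         sums = array(1, c(Q, Q, 1)),
                         counts = array(1, c(Q, Q, 1)),
                         arms = "chr1", Q = Q), class = "SaddleResult")
  st <- compartment_strength(flat, n_boot = 50, seed = 1)
  expect_equal(st$strength, 1)
  expect_equal(diff(range(st$bootstrap)), 0)
})

test_that("dissimilarity is zero on identity, symmetric, and orders noise vs flips", {
  smp_a <- make_comp_sample(0.8, seed = 15)
  smp_b <- make_comp_sample(0.8, seed = 16)
  cs_a <- compartment_score(smp_a$m, smp_a$gc)
  cs_b <- compartment_score(smp_b$m, smp_b$gc)
  expect_equal(compartment_dissimilarity(cs_a, cs_a), 0)
  expect_equal(compartment_dissimilarity(cs_a, cs_b),
               compartment_dissimilarity(cs_b, cs_a))
  # flipped profile on half the genome is more dissimilar than noise alone
  labels <- smp_a$spec$labels$chr1
  half <- seq_along(labels) > length(labels) / 2
  labels[half] <- -labels[half]
  spec_f <- synthetic_spec(c(chr1 = 60e6), 1e5, depth = 8e6, seed = 16,
                           compartments = list(labels = list(chr1 = labels),
                                               strength = 0.8))
  sim_f <- simulate_matrix(spec_f)
  cs_f <- compartment_score(balance(sim_f$matrix), smp_a$gc)
  expect_lt(compartment_dissimilarity(cs_a, cs_b),
            compartment_dissimilarity(cs_a, cs_f))
})

test_that("variance explained is 1 on identity and sign-blind, and matches a hand-computed toy", {
  smp <- make_comp_sample(0.8, seed = 17)
  cs <- compartment_score(smp$m, smp$gc)
  neg <- cs
  neg$score <- -neg$score
  expect_equal(compartment_variance_explained(cs, cs), 1)
  expect_equal(compartment_variance_explained(cs, neg), 1)
  # two-chromosome toy with known per-chromosome correlations
  bins <- bin_table(c(chr1 = 5e5, chr2 = 3e5), 1e5)
  a <- structure(list(bins = bins, score = c(1, 2, 3, 4, 5, 1, 2, 3),
                      arms = bins$chrom), class = "CompartmentScore")
  b <- structure(list(bins = bins, score = c(2, 1, 4, 3, 6, 3, 2, 1),
                      arms = bins$chrom), class = "CompartmentScore")
  r1 <- cor(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 6))
  r2 <- cor(c(1, 2, 3), c(3, 2, 1))
  expect_equal(compartment_variance_explained(a, b),
               (5e5 * r1^2 + 3e5 * r2^2) / 8e5)
})

test_that("delta-region finder applies the threshold, run length and sign-consistency rules", {
  bins <- bin_table(c(chr1 = 2e6), 2e4)  # 100 bins
  base <- rep(0, 100)
  shifted12 <- base; shifted12[41:52] <- 0.5
  shifted8 <- base; shifted8[41:48] <- 0.5
  expect_equal(nrow(delta_region_finder(list(list(base, base)), bins,
                                        0.25, 10)), 0)
  reg <- delta_region_finder(list(list(base, shifted12)), bins, 0.25, 10)
  expect_equal(nrow(reg), 1)
  expect_equal(reg$start, bins$start[41])
  expect_equal(reg$end, bins$end[52])
  expect_equal(reg$mean_delta, 0.5)
  expect_equal(nrow(delta_region_finder(list(list(base, shifted8)), bins,
                                        0.25, 10)), 0)
  # sign must be consistent across every pair
  down12 <- base; down12[41:52] <- -0.5
  expect_equal(nrow(delta_region_finder(
    list(list(base, shifted12), list(base, down12)), bins, 0.25, 10)), 0)
  expect_equal(nrow(delta_region_finder(
    list(list(base, shifted12), list(base, shifted12)), bins, 0.25, 10)), 1)
  expect_error(delta_region_finder(list(list(base, c(base, 0))), bins, 0.25, 10),
               "bin table")
})
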