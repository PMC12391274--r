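test_that("featureless spec gives pure decay in cis and constant trans", {
  spec <- synthetic_spec(c(chr1 = 10e6, chr2 = 10e6), 1e6,
                         decay_exponent = 1, depth = 1e6, seed = 1)
  e <- synthetic_expectation(spec, "chr1", scaled = FALSE)
  d <- abs(outer(1:10, 1:10, "-"))
  expect_equal(e, (d + 1)^-1, tolerance = 1e-12)
  et <- synthetic_expectation(spec, "chr1", "chr2", scaled = FALSE)
  expect_lt(diff(range(et)), 1e-12)
})

test_that("sampled matrices are symmetric, reproducible, and at target depth", {
  spec <- synthetic_spec(c(chr1 = 20e6, chr2 = 20e6), 5e5, depth = 2e6, seed = 9)
  sim <- simulate_matrix(spec)
  dn <- as_dense(sim$matrix, "chr1")
  expect_equal(dn, t(dn))
  total <- sum(sim$matrix$pixels$count)
  expect_lt(abs(total - spec$depth), 3 * sqrt(spec$depth))
  sim2 <- simulate_matrix(spec)
  expect_equal(sim2$matrix$pixels, sim$matrix$pixels)
})

test_that("a planted gain scales coverage by its copy ratio", {
  spec <- synthetic_spec(c(chr1 = 60e6, chr2 = 60e6), 1e6, depth = 4e6, seed = 3,
                         cnv_events = data.frame(chrom = "chr1", start = 20e6,
                                                 end = 50e6, ratio = 2))
  # analytic: expected coverage of gained bins / genome median expected coverage
  e1 <- synthetic_expectation(spec, "chr1")
  e2 <- synthetic_expectation(spec, "chr2")
  et <- synthetic_expectation(spec, "chr1", "chr2")
  cov <- c(rowSums(e1) + diag(e1) + rowSums(et),
           rowSums(e2) + diag(e2) + colSums(et))
  mid <- (spec$bins$start + spec$bins$end) / 2
  g <- spec$bins$chrom == "chr1" & mid >= 20e6 & mid < 50e6
  expect_equal(mean(cov[g]) / median(cov), 2, tolerance = 0.02)
  # sampled counts agree within sampling error
  scov <- marginals(simulate_matrix(spec)$matrix)
  expect_equal(mean(scov[g]) / median(scov), 2, tolerance = 0.05)
})

test_that("overlapping CNV events are rejected", {
  expect_error(
    synthetic_spec(c(chr1 = 60e6), 1e6,
                   cnv_events = data.frame(chrom = "chr1",
                                           start = c(10e6, 30e6),
                                           end = c(40e6, 50e6),
                                           ratio = c(2, 0.5))),
    "overlapping")
})

test_that("a translocation elevates exactly the orientation-selected quadrant", {
  for (ori in c("++", "-+", "--")) {
    spec <- synthetic_spec(
      c(chr1 = 30e6, chr2 = 30e6), 1e6, depth = 1e6, seed = 1,
      translocations = data.frame(chromA = "chr1", posA = 15e6,
                                  chromB = "chr2", posB = 20e6,
                                  orientation = ori))
    e <- synthetic_expectation(spec, "chr1", "chr2", scaled = FALSE)
    ba <- 16; bb <- 21
    quads <- c("++" = e[ba + 2, bb + 2], "+-" = e[ba + 2, bb - 2],
               "-+" = e[ba - 2, bb + 2], "--" = e[ba - 2, bb - 2])
    expect_equal(names(which.max(quads)), ori)
    expect_true(all(quads[names(quads) != ori] == spec$trans_level))
  }
})

test_that("checkerboard contrast of the expectation is strictly increasing in s", {
  contrast <- vapply(c(0.2, 0.5, 0.8), function(s) {
    spec <- synthetic_spec(c(chr1 = 20e6), 1e6, depth = 1e6, seed = 1,
                           compartments = list(block_size = 4e6, strength = s))
    e <- synthetic_expectation(spec, "chr1", scaled = FALSE)
    l <- spec$labels$chr1
    d <- abs(outer(seq_along(l), seq_along(l), "-"))
    base <- (d + 1)^-1
    same <- outer(l, l) > 0
    mean((e / base)[same]) / mean((e / base)[!same])
  }, numeric(1))
  expect_true(all(diff(contrast) > 0))
})

test_that("covariate tracks reflect compartments and are deterministic", {
  spec <- synthetic_spec(c(chr1 = 20e6), 2e5, depth = 1e6, seed = 4,
                         compartments = list(block_size = 2e6, strength = 0.5))
  tr <- simulate_tracks(spec)
  l <- spec$labels$chr1
  expect_gt(mean(tr$gc[l == 1]), mean(tr$gc[l == -1]))
  expect_true(all(tr$mappability > 0 & tr$mappability <= 1))
  expect_true(all(tr$sites >= 1 & tr$sites == round(tr$sites)))
  expect_identical(tr, simulate_tracks(spec))
})

test_that("simulated peak clusters align with planted anchors and obey the rules", {
  spec <- cluster_spec(e = 2)
  pk <- simulate_peaks(spec, peaks_per_cluster = 3, gap = 15000)
  cl <- call_clusters(pk)
  expect_true(all(cl$end - cl$start < 50000))
  expect_equal(nrow(cl), length(unique(paste(
    c(spec$cluster_pairs$chrom1, spec$cluster_pairs$chrom2),
    c(spec$cluster_pairs$start1, spec$cluster_pairs$start2)))))
  # clusters sit at the planted anchor midpoints
  anchors <- sort(unique(c((spec$cluster_pairs$start1 + spec$cluster_pairs$end1) / 2,
                           (spec$cluster_pairs$start2 + spec$cluster_pairs$end2) / 2)))
  expect_equal(sort(cl$mid), anchors, tolerance = 1e-6)
  # two peaks per cluster never satisfy the >= 3 peak rule
  pk2 <- simulate_peaks(spec, peaks_per_cluster = 2, gap = 15000)
  expect_equal(nrow(call_clusters(pk2)), 0)
  expect_equal(nrow(simulate_peaks(spec, n_clusters = 0)), 0)
})

test_that("peaks extending past the chromosome end are an error", {
  spec <- synthetic_spec(c(chr1 = 1e6), 2e4, depth = 1e5, seed = 1,
                         cluster_pairs = data.frame(
                           chrom1 = "chr1", start1 = 0, end1 = 2e4,
                           chrom2 = "chr1", start2 = 9.8e5, end2 = 1e6,
                           factor = 2))
  expect_error(simulate_peaks(spec, peaks_per_cluster = 5, gap = 15000),
               "past the end")
})
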