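test_that("tile counts match a brute-force sum over pixels and scale with depth", {
  spec <- synthetic_spec(c(chr1 = 10e6, chr2 = 10e6), 5e5, depth = 1e6, seed = 6)
  sim <- simulate_matrix(spec)
  m <- sim$matrix
  tracks <- simulate_tracks(spec)
  tiles <- tile_coverage(m, tracks, tile_size = 1e6)
  # oracle: loop over all pixels, adding the count once per mate end
  brute <- setNames(rep(0, nrow(tiles)), paste(tiles$chrom, tiles$start))
  for (k in seq_len(nrow(m$pixels))) {
    for (bin in c(m$pixels$bin1[k], m$pixels$bin2[k])) {
      key <- paste(m$bins$chrom[bin], floor(m$bins$start[bin] / 1e6) * 1e6)
      brute[key] <- brute[key] + m$pixels$count[k]
    }
  }
  expect_equal(tiles$read_count, unname(brute[paste(tiles$chrom, tiles$start)]))
  m2 <- m
  m2$pixels$count <- m2$pixels$count * 2
  tiles2 <- tile_coverage(m2, tracks, tile_size = 1e6)
  expect_equal(tiles2$read_count, tiles$read_count * 2)
})

test_that("coverage normalisation removes a pure restriction-site dependence", {
  set.seed(8)
  n <- 150
  sites <- rpois(n, 4000) + 1
  tiles <- data.frame(chrom = "chr1", start = (0:(n - 1)) * 1e6,
                      end = (1:n) * 1e6,
                      read_count = rpois(n, 20 * sites),
                      n_sites = sites,
                      gc = runif(n, 0.35, 0.45),
                      mappability = runif(n, 0.8, 1),
                      masked = FALSE)
  # near-zero residual deviance makes the smoother grumble about
  # convergence; the fit itself is what is under test
  nt <- suppressWarnings(normalise_coverage(tiles))
  expect_lt(max(abs(nt$log2_ratio)), 0.1)
  expect_equal(median(nt$log2_ratio), 0, tolerance = 1e-6)
})

test_that("normalisation leaves log2 ratios uncorrelated with covariates", {
  spec <- synthetic_spec(c(chr1 = 60e6, chr2 = 60e6), 1e6, depth = 6e6,
                         seed = 31, covariate_bias = TRUE)
  tiles <- tile_coverage(simulate_matrix(spec)$matrix, simulate_tracks(spec))
  nt <- normalise_coverage(tiles)
  ok <- !nt$masked
  for (covariate in c("gc", "mappability", "n_sites"))
    expect_lt(abs(cor(nt$log2_ratio[ok], nt[[covariate]][ok])), 0.1)
})

test_that("flat ratios give one neutral segment per chromosome", {
  set.seed(5)
  n <- 80
  tiles <- data.frame(chrom = rep(c("chr1", "chr2"), each = n / 2),
                      start = rep((0:(n / 2 - 1)) * 1e6, 2),
                      end = rep((1:(n / 2)) * 1e6, 2),
                      log2_ratio = rnorm(n, 0, 0.01), masked = FALSE)
  seg <- segment_cnv(tiles, seed = 2)$segments
  expect_equal(nrow(seg), 2)
  expect_true(all(seg$label == "neutral"))
})

test_that("gain/loss labels use strict log2(1.25) / log2(0.75) thresholds", {
  mk <- function(level) {
    data.frame(chrom = "chr1", start = (0:39) * 1e6, end = (1:40) * 1e6,
               log2_ratio = c(rep(0, 20), rep(level, 20)), masked = FALSE)
  }
  seg_on_boundary <- segment_cnv(mk(log2(1.25)), seed = 3)$segments
  expect_false(any(seg_on_boundary$label == "gain"))
  seg_above <- segment_cnv(mk(log2(1.6)), seed = 3)$segments
  expect_true(any(seg_above$label == "gain"))
  seg_low <- segment_cnv(mk(log2(0.75)), seed = 3)$segments
  expect_false(any(seg_low$label == "loss"))
  seg_below <- segment_cnv(mk(log2(0.5)), seed = 3)$segments
  expect_true(any(seg_below$label == "loss"))
  # a 1.1-fold region stays neutral
  seg_mild <- segment_cnv(mk(log2(1.1)), seed = 3)$segments
  expect_true(all(seg_mild$label == "neutral"))
})

test_that("segmentation recovers planted breakpoints within one tile", {
  set.seed(9)
  x <- c(rnorm(30, 0, 0.05), rnorm(20, 0.8, 0.05), rnorm(30, 0, 0.05))
  tiles <- data.frame(chrom = "chr1", start = (0:79) * 1e6, end = (1:80) * 1e6,
                      log2_ratio = x, masked = FALSE)
  seg <- segment_cnv(tiles, seed = 7)$segments
  gain <- seg[seg$label == "gain", ]
  expect_equal(nrow(gain), 1)
  expect_lte(abs(gain$start - 30e6), 1e6)
  expect_lte(abs(gain$end - 50e6), 1e6)
})

test_that("short chromosomes return a single unlabelled segment", {
  tiles <- data.frame(chrom = "chrM", start = (0:2) * 1e6, end = (1:3) * 1e6,
                      log2_ratio = c(0, 1, 0), masked = FALSE)
  seg <- segment_cnv(tiles, seed = 1)$segments
  expect_equal(nrow(seg), 1)
  expect_true(is.na(seg$label))
})
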