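# independent oracle: direct O(n^2 k^2) convolution with replicated borders
brute_conv <- function(mat, kern) {
  n <- nrow(mat); m <- ncol(mat)
  kh <- (nrow(kern) - 1) / 2
  out <- matrix(0, n, m)
  for (i in 1:n) for (j in 1:m) {
    acc <- 0
    for (di in -kh:kh) for (dj in -kh:kh) {
      ii <- min(max(i + di, 1), n)
      jj <- min(max(j + dj, 1), m)
      acc <- acc + mat[ii, jj] * kern[di + kh + 1, dj + kh + 1]
    }
    out[i, j] <- acc
  }
  out
}

brute_median3 <- function(mat) {
  n <- nrow(mat); m <- ncol(mat)
  out <- mat
  for (i in 1:n) for (j in 1:m) {
    vals <- c()
    for (di in -1:1) for (dj in -1:1)
      vals <- c(vals, mat[min(max(i + di, 1), n), min(max(j + dj, 1), m)])
    out[i, j] <- median(vals)
  }
  out
}

fake_image <- function(mat, raw = mat, stage = "residual") {
  n <- nrow(mat); m <- ncol(mat)
  bins <- rbind(data.frame(chrom = "chrA", start = (0:(n - 1)) * 5e5,
                           end = (1:n) * 5e5),
                data.frame(chrom = "chrB", start = (0:(m - 1)) * 5e5,
                           end = (1:m) * 5e5))
  structure(list(mat = mat, raw = raw, rows = 1:n, cols = n + 1:m,
                 chromA = "chrA", chromB = "chrB", stage = stage,
                 bins = bins, resolution = 5e5), class = "TransImage")
}

test_that("trans image filtering drops shallow bins", {
  spec <- trans_spec(seed = 41)
  m <- simulate_matrix(spec)$matrix
  img <- trans_image(m, "chr1", "chr2", min_bin_reads = 2000)
  cov <- marginals(m)
  expect_true(all(cov[img$rows] > 2000))
  expect_equal(nrow(img$mat), length(img$rows))
  img_hi <- trans_image(m, "chr1", "chr2", min_bin_reads = max(cov) + 1)
  expect_equal(nrow(img_hi$mat), 0)
})

test_that("NB-GLM normalisation maps observed == expected to 0 and applies the pseudo-count", {
  set.seed(2)
  mat <- matrix(20, 40, 40)
  zero_cells <- cbind(sample(40, 6), sample(40, 6))
  mat[zero_cells] <- 0
  img <- cnv_normalise_trans(fake_image(mat, stage = "raw"), phi = 20, seed = 1)
  # constant cells: observed == expected -> log2(1) = 0
  expect_lt(median(abs(img$mat[as.vector(mat) == 20])), 0.05)
  # obs = 0, expected ~ 20, phi = 20: log2(20 / 40) = -1
  expect_equal(unname(img$mat[as.vector(mat) == 0]),
               rep(-1, 6), tolerance = 0.1)
})

test_that("CNV normalisation flattens a whole-arm gain in trans", {
  spec <- synthetic_spec(c(chr1 = 60e6, chr2 = 60e6), 5e5, depth = 2.4e7,
                         seed = 42,
                         cnv_events = data.frame(chrom = "chr1", start = 0,
                                                 end = 30e6, ratio = 2))
  m <- simulate_matrix(spec)$matrix
  img <- cnv_normalise_trans(trans_image(m, "chr1", "chr2"), seed = 1)
  rm_ <- rowMeans(2^img$mat)
  gained <- img$rows <= 60
  expect_lt(abs(mean(rm_[gained]) / mean(rm_[!gained]) - 1), 0.1)
})

test_that("rank-1 removal cancels a separable image and halves a checkerboard", {
  set.seed(4)
  u <- runif(30, 0.5, 2); v <- runif(25, 0.5, 2)
  img <- compartment_normalise(fake_image(outer(u, v), stage = "cnv_normalised"))
  expect_lt(max(abs(img$mat)), 1e-6)
  # structureless image: residual ~ image minus its rank-1 part (svd oracle)
  noise <- matrix(rnorm(30 * 25), 30, 25)
  res <- compartment_normalise(fake_image(noise, stage = "cnv_normalised"))
  sv <- svd(noise)
  rank1 <- sv$d[1] * outer(sv$u[, 1], sv$v[, 1])
  expect_lt(max(abs(res$mat - (noise - rank1))), 0.2)
  # planted trans checkerboard: contrast reduced by at least half
  spec <- trans_spec(seed = 43, translocated = FALSE)
  m <- simulate_matrix(spec)$matrix
  ci <- cnv_normalise_trans(trans_image(m, "chr1", "chr2"), seed = 1)
  la <- spec$labels$chr1[ci$rows]
  lb <- spec$labels$chr2[ci$cols - 120]
  plaid <- function(x) mean(x[outer(la, lb) > 0]) - mean(x[outer(la, lb) < 0])
  before <- plaid(ci$mat)
  after <- plaid(compartment_normalise(ci)$mat)
  expect_lt(abs(after), abs(before) / 2)
})

test_that("corner response matches a brute-force oracle and is shift invariant", {
  set.seed(7)
  toy <- matrix(rnorm(15 * 15, 0, 0.1), 15, 15)
  toy[8:15, 8:15] <- toy[8:15, 8:15] + 2  # ideal step corner
  img <- corner_response(fake_image(toy), gain = 10)
  med <- brute_median3(toy)
  oracle <- matrix(1 * 4, 15, 15) * 0
  for (o in c("++", "+-", "-+", "--")) {
    k <- hicprog:::corner_kernel(7, o) * 10
    oracle <- oracle + pmax(brute_conv(med, k), 1)
  }
  expect_equal(img$mat, oracle, tolerance = 1e-6)
  # the step structure (corner and its edges) dominates the background;
  # note the summed-orientation kernel scores long step edges slightly above
  # the apex itself, so localisation downstream relies on raw counts
  bg <- img$mat[1:5, 1:5]
  expect_gt(img$mat[9, 9], 10 * max(bg))
  # zero-sum kernel: adding a constant changes nothing
  img2 <- corner_response(fake_image(toy + 5), gain = 10)
  expect_equal(img2$mat, img$mat, tolerance = 1e-6)
  # constant image: every orientation is floored
  img3 <- corner_response(fake_image(matrix(3, 15, 15)), floor_value = 1)
  expect_equal(unname(img3$mat[8, 8]), 4)
})

test_that("candidate extraction merges nearby areas and picks the max-count pixel", {
  resp <- matrix(0, 60, 60)
  resp[20, 20] <- 150
  resp[30, 30] <- 150  # 10 bins (5 Mb) away: dilation reach is 10 bins each
  raw <- matrix(10, 60, 60)
  raw[20, 20] <- 500
  raw[30, 30] <- 900
  img <- fake_image(resp, raw = raw, stage = "corner_response")
  cand <- find_candidates(img, binarise = 100, brush = 21)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$raw_count, 900)
  expect_equal(cand$binA, 30)
  # far-apart blobs stay separate
  resp2 <- matrix(0, 60, 60)
  resp2[10, 10] <- 150; resp2[50, 50] <- 150
  cand2 <- find_candidates(fake_image(resp2, raw = raw,
                                      stage = "corner_response"),
                           binarise = 100, brush = 21)
  expect_equal(nrow(cand2), 2)
  # nothing above threshold: empty result
  expect_equal(nrow(find_candidates(fake_image(matrix(1, 30, 30),
                                               raw = raw[1:30, 1:30],
                                               stage = "corner_response"))), 0)
})

test_that("the full caller is deterministic and localises a planted breakpoint", {
  spec <- trans_spec(seed = 44)
  sim <- simulate_matrix(spec)
  cand1 <- call_translocations_pair(sim$matrix, "chr1", "chr2", seed = 3)
  cand2 <- call_translocations_pair(sim$matrix, "chr1", "chr2", seed = 3)
  expect_identical(cand1, cand2)
  tA <- sim$truth$translocations$binA
  tB <- sim$truth$translocations$binB + 120
  expect_gte(nrow(cand1), 1)
  expect_true(any(abs(cand1$binA - tA) <= 1 & abs(cand1$binB - tB) <= 1))
})
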