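# Aggregate TAD analysis: size-rescaled, z-scored pile-up of TADs.

# z-score a dense symmetric O/E matrix per diagonal. Moments are estimated
# with an end margin excluded: balancing inflates bins near chromosome ends
# (they lack long-range partners), which would otherwise shift interior
# z-scores negative.
zscore_by_diagonal <- function(oe, trim = 0.05) {
  n <- nrow(oe)
  d <- abs(.row(dim(oe)) - .col(dim(oe)))
  v <- as.vector(oe)
  tr <- ceiling(trim * n)
  interior <- .row(dim(oe)) > tr & .row(dim(oe)) <= n - tr &
    .col(dim(oe)) > tr & .col(dim(oe)) <= n - tr
  ok <- !is.na(v) & as.vector(interior)
  mu <- rep(NA_real_, n); sd_ <- rep(NA_real_, n)
  agg_n <- rowsum(rep(1, sum(ok)), d[ok])
  agg_s <- rowsum(v[ok], d[ok])
  dd <- as.integer(rownames(agg_s))
  mu[dd + 1L] <- agg_s[, 1] / agg_n[, 1]
  agg_ss <- rowsum(v[ok]^2, d[ok])
  sd_[dd + 1L] <- sqrt(pmax(agg_ss[, 1] / agg_n[, 1] - (agg_s[, 1] / agg_n[, 1])^2, 0))
  z <- (v - mu[d + 1L]) / sd_[d + 1L]
  z[!is.finite(z)] <- NA
  matrix(z, n, n)
}

# K x L area-weighted aggregation matrix: row p of the result averages the
# source interval [(p-1)L/K, pL/K)
rescale_operator <- function(K, L) {
  A <- matrix(0, K, L)
  for (p in seq_len(K)) {
    lo <- (p - 1) * L / K
    hi <- p * L / K
    cells <- floor(lo):min(ceiling(hi) - 1, L - 1)
    w <- pmin(hi, cells + 1) - pmax(lo, cells)
    A[p, cells + 1] <- w / sum(w)
  }
  A
}

#' Aggregate TAD analysis (ATA)
#'
#' The cis O/E matrix of each chromosome is z-score normalised per
#' diagonal; each TAD, extended by `flank_fraction` of its length on both
#' sides, is rescaled to a K x K matrix by area-weighted interpolation and
#' the element-wise mean over TADs taken. Per-TAD strength is the mean of
#' the central TAD square minus the mean of the two flanking corner blocks
#' (left-flank x right-flank and its transpose); the bootstrap resamples
#' TADs with replacement.
#'
#' @param m a balanced `ContactMatrix`.
#' @param tads data frame with `chrom`, `start`, `end` (bp), e.g. the
#'   `tads` component of a [call_boundaries()] result.
#' @param K output matrix size.
#' @param flank_fraction flank length as a fraction of TAD length.
#' @param min_bins TADs shorter than this many bins are skipped.
#' @param n_boot bootstrap resamples of the mean strength.
#' @param seed RNG seed for the bootstrap.
#' @return object of class `ATAResult`: `matrix` (K x K mean z-score),
#'   `strength` (mean per-TAD strength), `per_tad`, `bootstrap`, `n_used`,
#'   `n_skipped`.
#' @export
ata <- function(m, tads, K = 100, flank_fraction = 0.5, min_bins = 3,
                n_boot = 1000, seed = 1) {
  res <- m$resolution
  acc_s <- matrix(0, K, K); acc_n <- matrix(0, K, K)
  per_tad <- numeric(0)
  n_skipped <- 0L
  cf1 <- floor(K * flank_fraction / (1 + 2 * flank_fraction)) + 1L
  cf2 <- ceiling(K * (1 + flank_fraction) / (1 + 2 * flank_fraction))
  prof <- expected_profile(m)
  for (chr in unique(tads$chrom)) {
    idx <- chrom_bins(m, chr)
    oe <- oe_dense(m, idx, prof$cis[[chr]])
    z <- zscore_by_diagonal(oe)
    n <- length(idx)
    td <- tads[tads$chrom == chr, ]
    for (k in seq_len(nrow(td))) {
      b1 <- floor(td$start[k] / res) + 1L
      b2 <- ceiling(td$end[k] / res)
      tlen <- b2 - b1 + 1L
      if (tlen < min_bins) { n_skipped <- n_skipped + 1L; next }
      f <- round(flank_fraction * tlen)
      w1 <- b1 - f; w2 <- b2 + f
      if (w1 < 1 || w2 > n) { n_skipped <- n_skipped + 1L; next }
      win <- z[w1:w2, w1:w2]
      L <- nrow(win)
      A <- rescale_operator(K, L)
      wmask <- !is.na(win)
      win0 <- win; win0[!wmask] <- 0
      num <- A %*% win0 %*% t(A)
      den <- A %*% wmask %*% t(A)
      r <- ifelse(den > 1e-9, num / den, NA)
      ok <- !is.na(r)
      acc_s[ok] <- acc_s[ok] + r[ok]
      acc_n[ok] <- acc_n[ok] + 1
      # strength: central TAD block vs the two flank-corner blocks
      ctr <- r[cf1:cf2, cf1:cf2]
      if (cf1 > 1 && cf2 < K) {
        corner <- c(r[1:(cf1 - 1), (cf2 + 1):K], r[(cf2 + 1):K, 1:(cf1 - 1)])
      } else corner <- NA
      per_tad <- c(per_tad, mean(ctr, na.rm = TRUE) - mean(corner, na.rm = TRUE))
    }
  }
  if (n_skipped > 0)
    message(sprintf("ata: %d TAD(s) skipped (short or at chromosome edge)", n_skipped))
  mat <- ifelse(acc_n > 0, acc_s / acc_n, NA)
  strength <- if (length(per_tad)) mean(per_tad, na.rm = TRUE) else NA_real_
  boot <- if (length(per_tad)) with_seed(seed, {
    vapply(seq_len(n_boot), function(b)
      mean(per_tad[sample.int(length(per_tad), replace = TRUE)], na.rm = TRUE),
      numeric(1))
  }) else numeric(0)
  structure(list(matrix = mat, strength = strength, per_tad = per_tad,
                 bootstrap = boot, n_used = length(per_tad),
                 n_skipped = n_skipped),
            class = "ATAResult")
}

#' @export
print.ATAResult <- function(x, ...) {
  cat(sprintf("ATAResult: %d TADs aggregated (%d skipped); strength %.3f\n",
              x$n_used, x$n_skipped, x$strength))
  invisible(x)
}
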