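#' Insulation score
#'
#' For each bin i, the mean balanced signal in the square window spanning
#' (i-w ... i-1) x (i+1 ... i+w) is computed (the sliding diamond), and the
#' insulation score is log2 of that mean over the chromosome-wide mean of
#' the same statistic. The score is missing within a window of chromosome
#' ends and at masked bins. Being a ratio statistic, it is invariant to
#' global scaling of the matrix.
#'
#' @param m a balanced `ContactMatrix` (typically at 20 kb).
#' @param window_bins half-window w in bins (default 25, i.e. 500 kb at
#'   20 kb resolution).
#' @return object of class `InsulationTrack`: `bins`, `score`, `window_bins`.
#' @export
insulation <- function(m, window_bins = 25) {
  w <- window_bins
  val <- balanced_values(m)
  score <- rep(NA_real_, nrow(m$bins))
  for (chr in unique(m$bins$chrom)) {
    idx <- chrom_bins(m, chr)
    n <- length(idx)
    if (n <= 2 * w) {
      warnf("insulation window (%d bins) too large for %s (%d bins)", w, chr, n)
      next
    }
    sel <- which(m$bins$chrom[m$pixels$bin1] == chr &
                   m$bins$chrom[m$pixels$bin2] == chr & !is.na(val))
    a <- m$pixels$bin1[sel] - idx[1] + 1L
    b <- m$pixels$bin2[sel] - idx[1] + 1L
    v <- val[sel]
    d <- b - a
    keep <- d >= 2 & d <= 2 * w
    a <- a[keep]; b <- b[keep]; v <- v[keep]
    # pixel (a, b) contributes to the diamond of every i with
    # a in [i-w, i-1] and b in [i+1, i+w]
    lo <- pmax(a + 1L, b - w)
    hi <- pmin(a + w, b - 1L)
    len <- hi - lo + 1L
    pos <- sequence(len) - 1L + rep(lo, len)
    sums <- numeric(n)
    agg <- rowsum(rep(v, len), pos)
    sums[as.integer(rownames(agg))] <- agg[, 1]
    valid_bin <- !is.na(m$weights[idx])
    # diamond denominator: number of valid pixel slots in the window
    npx <- vapply(seq_len(n), function(i) {
      if (i <= w || i > n - w) return(NA_real_)
      nl <- sum(valid_bin[(i - w):(i - 1)])
      nr <- sum(valid_bin[(i + 1):(i + w)])
      nl * nr
    }, numeric(1))
    stat <- sums / npx
    stat[!valid_bin] <- NA
    stat[!is.na(stat) & npx < 0.5 * w * w] <- NA  # mostly-masked windows
    mu <- mean(stat[!is.na(stat) & stat > 0])
    if (!is.finite(mu) || mu <= 0) next
    sc <- log2(stat / mu)
    sc[!is.finite(sc)] <- NA
    score[idx] <- sc
  }
  structure(list(bins = m$bins, score = score, window_bins = w),
            class = "InsulationTrack")
}

#' @export
print.InsulationTrack <- function(x, ...) {
  cat(sprintf("InsulationTrack: %d/%d bins scored (window %d bins)\n",
              sum(!is.na(x$score)), length(x$score), x$window_bins))
  invisible(x)
}

#' Call TAD boundaries from an insulation track
#'
#' Boundaries are strict local minima of the lightly smoothed insulation
#' score (3-bin moving average) whose prominence — the smaller of the two
#' flanking local maxima minus the minimum — is at least `min_strength`.
#' The default `-Inf` keeps every local minimum. TADs are the intervals
#' between consecutive boundaries.
#'
#' @param t an `InsulationTrack`.
#' @param min_strength minimum boundary prominence.
#' @param smooth_bins moving-average span (odd; 1 disables smoothing).
#' @return object of class `BoundarySet`: data frame `boundaries` with
#'   `chrom`, `bin` (1-based index within chromosome), `pos` (midpoint bp),
#'   `strength`; data frame `tads` with `chrom`, `start`, `end`.
#' @export
call_boundaries <- function(t, min_strength = -Inf, smooth_bins = 3) {
  stopifnot(inherits(t, "InsulationTrack"))
  bres <- list(); tres <- list()
  for (chr in unique(t$bins$chrom)) {
    idx <- which(t$bins$chrom == chr)
    s <- t$score[idx]
    if (all(is.na(s))) next
    sm <- if (smooth_bins > 1)
      stats::filter(s, rep(1 / smooth_bins, smooth_bins), sides = 2)
    else s
    sm <- as.numeric(sm)
    n <- length(sm)
    is_min <- rep(FALSE, n)
    for (i in 2:(n - 1)) {
      if (is.na(sm[i]) || is.na(sm[i - 1]) || is.na(sm[i + 1])) next
      is_min[i] <- sm[i] < sm[i - 1] && sm[i] < sm[i + 1]
    }
    cand <- which(is_min)
    if (!length(cand)) next
    strength <- vapply(cand, function(i) {
      left <- sm[max(1, i - 10):i]; right <- sm[i:min(n, i + 10)]
      min(max(left, na.rm = TRUE), max(right, na.rm = TRUE)) - sm[i]
    }, numeric(1))
    keep <- strength >= min_strength
    cand <- cand[keep]; strength <- strength[keep]
    if (!length(cand)) next
    bres[[chr]] <- data.frame(
      chrom = chr, bin = cand,
      pos = (t$bins$start[idx[cand]] + t$bins$end[idx[cand]]) / 2,
      strength = strength)
    edges <- c(0, t$bins$end[idx[cand]], max(t$bins$end[idx]))
    tres[[chr]] <- data.frame(chrom = chr, start = edges[-length(edges)],
                              end = edges[-1])
  }
  boundaries <- if (length(bres)) do.call(rbind, bres)
    else data.frame(chrom = character(), bin = integer(), pos = numeric(),
                    strength = numeric())
  rownames(boundaries) <- NULL
  tads <- if (length(tres)) do.call(rbind, tres)
    else data.frame(chrom = character(), start = numeric(), end = numeric())
  rownames(tads) <- NULL
  structure(list(boundaries = boundaries, tads = tads),
            class = "BoundarySet")
}

#' @export
print.BoundarySet <- function(x, ...) {
  cat(sprintf("BoundarySet: %d boundaries, %d TADs\n",
              nrow(x$boundaries), nrow(x$tads)))
  invisible(x)
}

#' Jaccard index of boundary positions with positional tolerance
#'
#' Boundaries of both sets are pooled and transitively (single-linkage)
#' merged: any two boundaries within `merge_window` of each other belong to
#' the same unique site. The index is the number of sites containing
#' boundaries from both sets over the number of sites overall.
#'
#' @param a,b `BoundarySet` objects on the same genome.
#' @param merge_window merge distance in bp.
#' @return scalar in \[0, 1\]. Both sets empty gives 1; exactly one empty
#'   gives 0 with a warning.
#' @export
boundary_jaccard <- function(a, b, merge_window = 60000) {
  pa <- a$boundaries; pb <- b$boundaries
  if (nrow(pa) == 0 && nrow(pb) == 0) return(1)
  if (nrow(pa) == 0 || nrow(pb) == 0) {
    warnf("one boundary set is empty; Jaccard index defined as 0")
    return(0)
  }
  pool <- rbind(data.frame(chrom = pa$chrom, pos = pa$pos, set = "a"),
                data.frame(chrom = pb$chrom, pos = pb$pos, set = "b"))
  pool <- pool[order(pool$chrom, pool$pos), ]
  new_site <- c(TRUE, pool$chrom[-1] != pool$chrom[-nrow(pool)] |
                  diff(pool$pos) > merge_window)
  site <- cumsum(new_site)
  has_a <- tapply(pool$set == "a", site, any)
  has_b <- tapply(pool$set == "b", site, any)
  sum(has_a & has_b) / length(has_a)
}
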