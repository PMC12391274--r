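# Binding-site cluster calling and paired-end spatial chromatin analysis.

#' Call dense clusters of binding peaks
#'
#' A cluster is a maximal run of at least `min_peaks` peaks whose successive
#' midpoint distances are all below `max_gap`.
#'
#' @param peaks data frame with `chrom`, `start`, `end`.
#' @param min_peaks minimum number of peaks in a cluster.
#' @param max_gap maximum distance between successive peak midpoints (bp);
#'   gaps equal to `max_gap` break the run.
#' @return data frame with `chrom`, `start`, `end`, `n_peaks`, `mid`.
#' @export
call_clusters <- function(peaks, min_peaks = 3, max_gap = 20000) {
  if (nrow(peaks) == 0)
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      n_peaks = integer(), mid = numeric()))
  o <- order(peaks$chrom, peaks$start)
  if (any(o != seq_len(nrow(peaks)))) {
    message("call_clusters: input peaks were not sorted; sorting")
    peaks <- peaks[o, ]
  }
  out <- list()
  for (chr in unique(peaks$chrom)) {
    p <- peaks[peaks$chrom == chr, ]
    mid <- (p$start + p$end) / 2
    brk <- c(TRUE, diff(mid) >= max_gap)
    run <- cumsum(brk)
    for (rr in unique(run)) {
      sel <- run == rr
      if (sum(sel) < min_peaks) next
      out[[length(out) + 1L]] <- data.frame(
        chrom = chr, start = min(p$start[sel]), end = max(p$end[sel]),
        n_peaks = sum(sel), mid = mean(range(mid[sel])))
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      n_peaks = integer(), mid = numeric()))
  do.call(rbind, out)
}

#' Paired-end spatial chromatin analysis (distal pairwise pile-up)
#'
#' For every same-chromosome cluster pair with midpoint separation above
#' `dist_min`, the W x W O/E submatrix centred on the pair's bin pixel is
#' extracted and the element-wise mean over pairs taken. Enrichment is the
#' mean of the central `fg` x `fg` block minus the mean of the four corner
#' quadrants outside the central rows/columns; the bootstrap resamples
#' pairs with replacement. Windows crossing a chromosome end, or with more
#' than half of their pixels masked, are dropped.
#'
#' @param m a balanced `ContactMatrix` (typically at 20 kb).
#' @param clusters data frame from [call_clusters()].
#' @param W window size in bins (odd).
#' @param dist_min minimum midpoint separation (bp).
#' @param fg foreground block size in bins (odd).
#' @param n_boot bootstrap resamples.
#' @param seed RNG seed for the bootstrap.
#' @return object of class `PEScanResult`: `matrix` (W x W mean O/E),
#'   `n_pairs`, `enrichment`, `bootstrap`.
#' @export
pe_scan <- function(m, clusters, W = 21, dist_min = 3e6, fg = 9,
                    n_boot = 1000, seed = 1) {
  stopifnot(W %% 2 == 1, fg %% 2 == 1, fg < W)
  res <- m$resolution
  h <- (W - 1) / 2
  prof <- expected_profile(m)
  windows <- list()
  for (chr in unique(clusters$chrom)) {
    cl <- clusters[clusters$chrom == chr, ]
    if (nrow(cl) < 2) next
    idx <- chrom_bins(m, chr)
    n <- length(idx)
    oe <- oe_dense(m, idx, prof$cis[[chr]])
    bin <- floor(cl$mid / res) + 1L
    for (i in seq_len(nrow(cl) - 1)) for (j in (i + 1):nrow(cl)) {
      if (abs(cl$mid[j] - cl$mid[i]) <= dist_min) next
      bi <- bin[i]; bj <- bin[j]
      if (bi - h < 1 || bi + h > n || bj - h < 1 || bj + h > n) next
      win <- oe[(bi - h):(bi + h), (bj - h):(bj + h)]
      if (mean(is.na(win)) > 0.5) next
      windows[[length(windows) + 1L]] <- win
    }
  }
  n_pairs <- length(windows)
  if (n_pairs == 0)
    return(structure(list(matrix = matrix(NA_real_, W, W), n_pairs = 0L,
                          enrichment = NA_real_, bootstrap = numeric(0)),
                     class = "PEScanResult"))
  arr <- array(unlist(windows), dim = c(W, W, n_pairs))
  pile <- apply(arr, c(1, 2), mean, na.rm = TRUE)
  enrichment <- pescan_quantify(pile, fg = fg)
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      sel <- sample.int(n_pairs, replace = TRUE)
      pescan_quantify(apply(arr[, , sel, drop = FALSE], c(1, 2), mean,
                            na.rm = TRUE), fg = fg)
    }, numeric(1))
  })
  structure(list(matrix = pile, n_pairs = n_pairs, enrichment = enrichment,
                 bootstrap = boot),
            class = "PEScanResult")
}

#' @export
print.PEScanResult <- function(x, ...) {
  cat(sprintf("PEScanResult: %d cluster pairs; enrichment %.4f\n",
              x$n_pairs, x$enrichment))
  invisible(x)
}

#' Centre-versus-quadrants quantification of a pile-up matrix
#'
#' Mean of the central `fg` x `fg` block minus the mean over the four
#' corner quadrants outside the central rows and columns.
#'
#' @param pile odd-sized square pile-up matrix.
#' @param fg foreground block size (odd, smaller than the matrix).
#' @return scalar enrichment.
#' @export
pescan_quantify <- function(pile, fg = 9) {
  W <- nrow(pile)
  stopifnot(ncol(pile) == W, W %% 2 == 1, fg %% 2 == 1, fg < W)
  c0 <- (W + 1) / 2
  fh <- (fg - 1) / 2
  ctr <- pile[(c0 - fh):(c0 + fh), (c0 - fh):(c0 + fh)]
  lo <- 1:(c0 - fh - 1); hi <- (c0 + fh + 1):W
  quad <- c(pile[lo, lo], pile[lo, hi], pile[hi, lo], pile[hi, hi])
  mean(ctr, na.rm = TRUE) - mean(quad, na.rm = TRUE)
}
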