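#' A/B compartment score
#'
#' Per chromosome arm: the cis observed/expected matrix is computed over
#' unmasked bins, its Pearson correlation matrix taken, and the leading
#' eigenvector extracted and scaled by the square root of the leading
#' eigenvalue. The sign is fixed so that the score correlates positively
#' with GC content on every arm; when a reference score is supplied, any arm
#' whose score correlates negatively with the reference is additionally
#' flipped (cross-sample synchronisation). Arms with fewer than `min_bins`
#' valid bins get a missing score, with a warning.
#'
#' @param m a balanced `ContactMatrix` (typically at 100 kb).
#' @param gc numeric GC fraction per bin.
#' @param reference optional `CompartmentScore` to synchronise signs with.
#' @param arms arm labels from [split_arms()]; defaults to one arm per
#'   chromosome.
#' @param min_bins minimum valid bins per arm.
#' @return object of class `CompartmentScore`: `bins`, `score` (per bin, NA
#'   where masked), `arms`, `eigenvalues` (named per arm), `var_share`
#'   (leading eigenvalue / total).
#' @export
compartment_score <- function(m, gc, reference = NULL, arms = NULL,
                              min_bins = 20) {
  stopifnot(length(gc) == nrow(m$bins))
  if (is.null(arms)) arms <- m$bins$chrom
  prof <- expected_profile(m, arms = arms)
  score <- rep(NA_real_, nrow(m$bins))
  eigenvalues <- c()
  var_share <- c()
  for (g in unique(arms[!is.na(arms)])) {
    bins_idx <- which(!is.na(arms) & arms == g)
    oe <- oe_dense(m, bins_idx, prof$cis[[g]])
    valid <- which(!is.na(m$weights[bins_idx]))
    if (length(valid) < min_bins) {
      warnf("arm %s has %d valid bins (< %d); compartment score left missing",
            g, length(valid), min_bins)
      next
    }
    sub <- oe[valid, valid, drop = FALSE]
    cc <- suppressWarnings(stats::cor(sub, use = "pairwise.complete.obs"))
    cc[!is.finite(cc)] <- 0
    ev <- eigen(cc, symmetric = TRUE)
    v1 <- ev$vectors[, 1] * sqrt(max(ev$values[1], 0))
    gsub <- gc[bins_idx][valid]
    r_gc <- suppressWarnings(stats::cor(v1, gsub))
    if (is.finite(r_gc) && r_gc < 0) v1 <- -v1
    if (!is.null(reference)) {
      ref <- reference$score[bins_idx][valid]
      r_ref <- suppressWarnings(stats::cor(v1, ref, use = "complete.obs"))
      if (is.finite(r_ref) && r_ref < 0) v1 <- -v1
    }
    score[bins_idx[valid]] <- v1
    eigenvalues[g] <- ev$values[1]
    var_share[g] <- ev$values[1] / sum(pmax(ev$values, 0))
  }
  structure(list(bins = m$bins, score = score, arms = arms,
                 eigenvalues = eigenvalues, var_share = var_share),
            class = "CompartmentScore")
}

#' @export
print.CompartmentScore <- function(x, ...) {
  cat(sprintf("CompartmentScore: %d/%d bins scored on %d arm(s)\n",
              sum(!is.na(x$score)), length(x$score), length(x$eigenvalues)))
  invisible(x)
}

#' Saddle plot: mean O/E by compartment-score quantile pair
#'
#' Bins of each arm are ranked by compartment score into `Q` equal-occupancy
#' quantiles (quantile 1 = most B-like); the mean cis O/E for every quantile
#' pair is accumulated per arm and averaged over all arms. Arms with fewer
#' valid bins than `Q` are skipped.
#'
#' @param m a balanced `ContactMatrix` on the same bins as `cs`.
#' @param cs a `CompartmentScore`.
#' @param Q number of quantile bins.
#' @return object of class `SaddleResult`: `matrix` (Q x Q pooled mean O/E),
#'   `sums`/`counts` (Q x Q x n_arm accumulators for bootstrapping), `arms`
#'   (names of arms used), `Q`.
#' @export
saddle <- function(m, cs, Q = 50) {
  stopifnot(inherits(cs, "CompartmentScore"),
            nrow(m$bins) == nrow(cs$bins))
  arms <- cs$arms
  prof <- expected_profile(m, arms = arms)
  used <- character()
  sums <- list(); counts <- list()
  for (g in unique(arms[!is.na(arms)])) {
    bins_idx <- which(!is.na(arms) & arms == g)
    valid <- which(!is.na(m$weights[bins_idx]) & !is.na(cs$score[bins_idx]))
    if (length(valid) < Q) {
      message(sprintf("saddle: arm %s has %d valid bins (< Q = %d); skipped",
                      g, length(valid), Q))
      next
    }
    oe <- oe_dense(m, bins_idx, prof$cis[[g]])[valid, valid, drop = FALSE]
    q <- ceiling(rank(cs$score[bins_idx][valid], ties.method = "first") /
                   length(valid) * Q)
    s <- matrix(0, Q, Q); n <- matrix(0, Q, Q)
    ut <- which(upper.tri(oe) & !is.na(oe), arr.ind = TRUE)
    if (nrow(ut)) {
      qi <- q[ut[, 1]]; qj <- q[ut[, 2]]
      ii <- pmin(qi, qj); jj <- pmax(qi, qj)
      key <- (ii - 1) * Q + jj
      agg_s <- rowsum(oe[ut], key)
      agg_n <- rowsum(rep(1, nrow(ut)), key)
      k <- as.integer(rownames(agg_s))
      s[cbind((k - 1) %/% Q + 1, (k - 1) %% Q + 1)] <- agg_s[, 1]
      n[cbind((k - 1) %/% Q + 1, (k - 1) %% Q + 1)] <- agg_n[, 1]
      s <- s + t(s) - diag(diag(s)); n <- n + t(n) - diag(diag(n))
    }
    used <- c(used, g)
    sums[[g]] <- s; counts[[g]] <- n
  }
  if (!length(used)) stopf("no arm had enough valid bins for a saddle")
  S <- array(unlist(sums), dim = c(Q, Q, length(used)))
  N <- array(unlist(counts), dim = c(Q, Q, length(used)))
  pooled <- apply(S, c(1, 2), sum) / pmax(apply(N, c(1, 2), sum), 1)
  pooled[apply(N, c(1, 2), sum) == 0] <- NA
  structure(list(matrix = pooled, sums = S, counts = N, arms = used, Q = Q),
            class = "SaddleResult")
}

#' @export
print.SaddleResult <- function(x, ...) {
  cat(sprintf("SaddleResult: %d x %d over %d arm(s)\n", x$Q, x$Q, length(x$arms)))
  invisible(x)
}

# corner means of one arm's saddle accumulators
saddle_corners <- function(s, n, Q, k) {
  lo <- 1:k; hi <- (Q - k + 1):Q
  blk <- function(ri, ci) {
    tot <- sum(n[ri, ci])
    if (tot == 0) NA_real_ else sum(s[ri, ci]) / tot
  }
  c(BB = blk(lo, lo), AA = blk(hi, hi), AB = blk(lo, hi))
}

#' Compartment strength with arm bootstrap
#'
#' Strength = (mean AA corner + mean BB corner) / (2 x mean AB corner),
#' using the extreme `corner_fraction` of quantiles on each side. The point
#' estimate is the mean of per-arm strengths; the bootstrap resamples arms
#' with replacement and recomputes the over-arm average.
#'
#' @param s a `SaddleResult`.
#' @param corner_fraction fraction of quantiles in each corner.
#' @param n_boot number of bootstrap resamples.
#' @param seed RNG seed for the bootstrap.
#' @return list with `strength` (point estimate), `per_arm` (named vector),
#'   and `bootstrap` (numeric vector of length `n_boot`).
#' @export
compartment_strength <- function(s, corner_fraction = 0.2, n_boot = 1000,
                                 seed = 1) {
  stopifnot(inherits(s, "SaddleResult"))
  k <- max(1L, round(s$Q * corner_fraction))
  narm <- length(s$arms)
  per_arm <- vapply(seq_len(narm), function(a) {
    co <- saddle_corners(s$sums[, , a], s$counts[, , a], s$Q, k)
    if (any(is.na(co)) || co["AB"] == 0)
      stopf("empty saddle corner block on arm %s", s$arms[a])
    (co["AA"] + co["BB"]) / (2 * co["AB"])
  }, numeric(1))
  names(per_arm) <- s$arms
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b)
      mean(per_arm[sample.int(narm, narm, replace = TRUE)]), numeric(1))
  })
  list(strength = mean(per_arm), per_arm = per_arm, bootstrap = boot)
}

# per-chromosome rank-normalised score on shared valid bins
rank_norm_pair <- function(a, b) {
  stopifnot(nrow(a$bins) == nrow(b$bins))
  shared <- which(!is.na(a$score) & !is.na(b$score))
  if (!length(shared)) stopf("no shared unmasked bins between the two scores")
  shared
}

#' Pairwise compartment dissimilarity (weighted mean |delta rank|)
#'
#' Scores of both samples are rank-normalised to \[0, 1\] per chromosome on
#' their shared valid bins; the per-chromosome mean absolute difference is
#' combined as a chromosome-length-weighted mean. 0 = identical
#' compartmentalisation; larger = more dissimilar.
#'
#' @param a,b `CompartmentScore` objects on the same bin table.
#' @return scalar dissimilarity.
#' @export
compartment_dissimilarity <- function(a, b) {
  shared <- rank_norm_pair(a, b)
  bins <- a$bins
  chroms <- unique(bins$chrom)
  val <- 0; wsum <- 0
  for (chr in chroms) {
    idx <- shared[bins$chrom[shared] == chr]
    if (length(idx) < 2) next
    ra <- rank(a$score[idx]) / length(idx)
    rb <- rank(b$score[idx]) / length(idx)
    w <- max(bins$end[bins$chrom == chr])
    val <- val + w * mean(abs(ra - rb))
    wsum <- wsum + w
  }
  if (wsum == 0) stopf("no chromosome with shared scored bins")
  val / wsum
}

#' Compartment-score variance explained between two samples
#'
#' Pearson correlation of the two scores per chromosome; the squared
#' correlations are combined as a chromosome-length-weighted mean.
#' Sign-blind by construction (R^2).
#'
#' @param a,b `CompartmentScore` objects on the same bin table.
#' @return scalar in \[0, 1\].
#' @export
compartment_variance_explained <- function(a, b) {
  shared <- rank_norm_pair(a, b)
  bins <- a$bins
  val <- 0; wsum <- 0
  for (chr in unique(bins$chrom)) {
    idx <- shared[bins$chrom[shared] == chr]
    if (length(idx) < 3) next
    sa <- a$score[idx]; sb <- b$score[idx]
    if (stats::sd(sa) == 0 || stats::sd(sb) == 0) {
      message(sprintf("variance explained: constant score on %s; skipped", chr))
      next
    }
    r <- stats::cor(sa, sb)
    w <- max(bins$end[bins$chrom == chr])
    val <- val + w * r^2
    wsum <- wsum + w
  }
  if (wsum == 0) stopf("no chromosome with variable shared scores")
  val / wsum
}

#' Find regions of consistent score difference between sample pairs
#'
#' For each supplied pair of per-bin tracks (e.g. insulation or compartment
#' scores of a primary/metastasis pair), the per-bin difference (second
#' minus first) is computed. A bin qualifies when every pair's difference
#' exceeds `threshold` in magnitude with the same sign across all pairs.
#' Maximal runs of at least `min_bins` consecutive qualifying bins (within a
#' chromosome) are returned.
#'
#' @param track_pairs list of two-element lists/pairs of numeric per-bin
#'   vectors, all on the bin table `bins`.
#' @param bins the shared bin table.
#' @param threshold minimum |difference| per pair.
#' @param min_bins minimum run length in bins.
#' @return data frame with `chrom`, `start`, `end`, `n_bins`, `mean_delta`,
#'   `direction`; zero rows when nothing qualifies.
#' @export
delta_region_finder <- function(track_pairs, bins, threshold = 0.25,
                                min_bins = 10) {
  stopifnot(length(track_pairs) >= 1)
  n <- nrow(bins)
  deltas <- lapply(track_pairs, function(p) {
    if (length(p[[1]]) != n || length(p[[2]]) != n)
      stopf("track pair not on the supplied bin table")
    p[[2]] - p[[1]]
  })
  dmat <- do.call(cbind, deltas)
  up <- rowSums(dmat > threshold) == ncol(dmat)
  dn <- rowSums(dmat < -threshold) == ncol(dmat)
  up[is.na(up)] <- FALSE; dn[is.na(dn)] <- FALSE
  qual <- up | dn
  out <- list()
  for (chr in unique(bins$chrom)) {
    idx <- which(bins$chrom == chr)
    q <- qual[idx]
    r <- rle(q)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in which(r$values & r$lengths >= min_bins)) {
      span <- idx[starts[k]:ends[k]]
      out[[length(out) + 1L]] <- data.frame(
        chrom = chr, start = bins$start[span[1]], end = bins$end[span[length(span)]],
        n_bins = length(span), mean_delta = mean(dmat[span, ]),
        direction = if (up[span[1]]) "up" else "down")
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      n_bins = integer(), mean_delta = numeric(),
                      direction = character()))
  do.call(rbind, out)
}
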