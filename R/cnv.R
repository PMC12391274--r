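# Copy-number estimation from Hi-C coverage.

#' Tile genome coverage with covariates
#'
#' Counts both read ends per tile from the binned matrix marginals (a
#' pair's two mates are counted individually) and attaches the mean GC,
#' mean mappability and summed restriction-site count of the covariate
#' tracks. Tiles with a missing covariate, or mean mappability below
#' `mappability_min`, are masked.
#'
#' @param m a `ContactMatrix` whose resolution divides `tile_size`.
#' @param tracks data frame aligned to `m`'s bins with columns `gc`,
#'   `mappability`, `sites` (as produced by [simulate_tracks()]).
#' @param tile_size tile size in bp (default 1 Mb).
#' @param mappability_min tiles below this mean mappability are masked.
#' @return data frame of tiles: `chrom`, `start`, `end`, `read_count`,
#'   `n_sites`, `gc`, `mappability`, `masked`.
#' @export
tile_coverage <- function(m, tracks, tile_size = 1e6, mappability_min = 0.5) {
  stopifnot(nrow(tracks) == nrow(m$bins),
            tile_size %% m$resolution == 0)
  cov <- marginals(m)
  tile <- paste(m$bins$chrom, floor(m$bins$start / tile_size))
  key <- sort(unique(tile))
  ord <- match(key, tile)  # first bin of each tile
  out <- data.frame(
    chrom = m$bins$chrom[ord],
    start = floor(m$bins$start[ord] / tile_size) * tile_size)
  out$end <- pmin(out$start + tile_size,
                  vapply(out$chrom, function(ch) max(m$bins$end[m$bins$chrom == ch]),
                         numeric(1)))
  tt <- factor(tile, levels = key)
  out$read_count <- as.numeric(tapply(cov, tt, sum))
  out$n_sites <- as.numeric(tapply(tracks$sites, tt, sum))
  out$gc <- as.numeric(tapply(tracks$gc, tt, mean))
  out$mappability <- as.numeric(tapply(tracks$mappability, tt, mean))
  out$masked <- is.na(out$gc) | is.na(out$mappability) | is.na(out$n_sites) |
    out$mappability < mappability_min
  out <- out[order(out$chrom, out$start), ]
  rownames(out) <- NULL
  out
}

#' Regress covariates out of tile coverage
#'
#' Fits an additive smooth Poisson model of read count on GC, mappability
#' and restriction-site count over unmasked tiles; normalised count is the
#' observed count over the fitted value, and the log2 ratio is taken
#' against the genome-wide median of normalised counts (so the median log2
#' ratio is 0 by construction). The fit is two-pass: after a first fit,
#' tiles whose provisional |log2 ratio| exceeds `refit_threshold` (copy
#' number changes) are excluded and the model refitted on the neutral core,
#' so genuine gains and losses do not bend the covariate curves. Constant
#' covariates are dropped from the model.
#'
#' @param tiles data frame from [tile_coverage()].
#' @param k basis dimension of each smooth term.
#' @param refit_threshold provisional |log2 ratio| above which a tile is
#'   held out of the second fitting pass.
#' @return `tiles` with `normalised_count` and `log2_ratio` columns added
#'   (NA on masked tiles).
#' @export
normalise_coverage <- function(tiles, k = 5, refit_threshold = 0.3) {
  ok <- !tiles$masked
  if (sum(ok) < 100)
    stopf("need at least 100 unmasked tiles (%d available)", sum(ok))
  covars <- c("gc", "mappability", "n_sites")
  use <- covars[vapply(covars, function(cn) stats::sd(tiles[[cn]][ok]) > 0, TRUE)]
  for (cn in setdiff(covars, use))
    message(sprintf("normalise_coverage: covariate %s is constant; dropped", cn))
  fit_mu <- function(fit_rows) {
    if (!length(use)) return(rep(mean(tiles$read_count[fit_rows]), sum(ok)))
    form <- stats::as.formula(paste(
      "read_count ~", paste(sprintf("s(%s, k = %d)", use, k), collapse = " + ")))
    fit <- mgcv::gam(form, family = stats::poisson(), data = tiles[fit_rows, ])
    as.numeric(stats::predict(fit, newdata = tiles[ok, ], type = "response"))
  }
  ratio_of <- function(mu) {
    norm <- tiles$read_count[ok] / mu
    log2(norm / stats::median(norm))
  }
  l2 <- ratio_of(fit_mu(which(ok)))
  core <- which(ok)[abs(l2) <= refit_threshold]
  if (length(core) >= 50 && length(core) < sum(ok))
    mu <- fit_mu(core)
  else mu <- fit_mu(which(ok))
  tiles$normalised_count <- NA_real_
  tiles$normalised_count[ok] <- tiles$read_count[ok] / mu
  med <- stats::median(tiles$normalised_count[ok])
  tiles$log2_ratio <- NA_real_
  pos <- ok & tiles$normalised_count > 0
  tiles$log2_ratio[pos] <- log2(tiles$normalised_count[pos] / med)
  tiles
}

# max two-sample t statistic over all splits of x; returns c(stat, split)
best_split <- function(x, min_seg = 2) {
  n <- length(x)
  if (n < 2 * min_seg) return(c(0, NA))
  cs <- cumsum(x); cs2 <- cumsum(x^2)
  ks <- min_seg:(n - min_seg)
  n1 <- ks; n2 <- n - ks
  s1 <- cs[ks]; s2 <- cs[n] - s1
  m1 <- s1 / n1; m2 <- s2 / n2
  ss1 <- cs2[ks] - s1^2 / n1
  ss2 <- (cs2[n] - cs2[ks]) - s2^2 / n2
  pool <- (ss1 + ss2) / pmax(n - 2, 1)
  t2 <- (m1 - m2)^2 / (pool * (1 / n1 + 1 / n2) + 1e-12)
  k <- which.max(t2)
  c(sqrt(t2[k]), ks[k])
}

#' Segment tile log2 ratios by recursive binary splitting
#'
#' Within each chromosome, the split maximising the two-sample t statistic
#' of the log2 ratio is accepted when its permutation p value is below
#' `alpha`; accepted splits are recursed on both sides. Segments are
#' labelled `gain` when the mean log2 ratio exceeds log2(1.25), `loss` when
#' it is below log2(0.75), and `neutral` otherwise (boundary values are
#' neutral). Chromosomes with fewer than `min_tiles` unmasked tiles return
#' a single unlabelled segment.
#'
#' @param tiles data frame from [normalise_coverage()].
#' @param alpha permutation p-value threshold for accepting a split.
#' @param n_perm number of permutations per tested split.
#' @param seed RNG seed for the permutation test.
#' @param gain_threshold,loss_threshold log2-ratio label thresholds.
#' @param min_tiles minimum unmasked tiles per chromosome.
#' @param undo_sd merge adjacent segments whose means differ by fewer than
#'   this many noise standard deviations (0 disables); a minimum-effect
#'   floor of 0.1 log2 units applies regardless, since differences well
#'   below the gain/loss thresholds (about +/-0.32) are not callable
#'   events.
#' @return object of class `SegmentSet`: data frame `segments` with
#'   `chrom`, `start`, `end`, `mean_log2`, `n_tiles`, `label`.
#' @export
segment_cnv <- function(tiles, alpha = 0.01, n_perm = 1000, seed = 1,
                        gain_threshold = log2(1.25),
                        loss_threshold = log2(0.75), min_tiles = 5,
                        undo_sd = 2) {
  segs <- list()
  with_seed(seed, {
    for (chr in unique(tiles$chrom)) {
      td <- tiles[tiles$chrom == chr & !tiles$masked & !is.na(tiles$log2_ratio), ]
      nt <- nrow(td)
      if (nt < min_tiles) {
        segs[[length(segs) + 1L]] <- data.frame(
          chrom = chr,
          start = min(tiles$start[tiles$chrom == chr]),
          end = max(tiles$end[tiles$chrom == chr]),
          mean_log2 = if (nt > 0) mean(td$log2_ratio) else NA_real_,
          n_tiles = nt, label = NA_character_)
        next
      }
      x <- td$log2_ratio
      breaks <- sort(unique(c(0, nt, segment_recurse(x, 1, nt, alpha, n_perm))))
      if (undo_sd > 0) breaks <- undo_splits(x, breaks, undo_sd)
      for (b in seq_len(length(breaks) - 1)) {
        lo <- breaks[b] + 1; hi <- breaks[b + 1]
        mu <- mean(x[lo:hi])
        lab <- if (mu > gain_threshold) "gain"
          else if (mu < loss_threshold) "loss" else "neutral"
        segs[[length(segs) + 1L]] <- data.frame(
          chrom = chr, start = td$start[lo], end = td$end[hi],
          mean_log2 = mu, n_tiles = hi - lo + 1, label = lab)
      }
    }
  })
  segments <- do.call(rbind, segs)
  rownames(segments) <- NULL
  structure(list(segments = segments), class = "SegmentSet")
}

# undo splits whose segment means differ by less than undo_sd noise SDs
# (noise SD estimated from first differences); merges the weakest adjacent
# pair repeatedly, as CBS implementations do
undo_splits <- function(x, breaks, undo_sd, min_effect = 0.1) {
  if (length(breaks) <= 2 || undo_sd <= 0) return(breaks)
  sigma <- stats::mad(diff(x)) / sqrt(2)
  if (!is.finite(sigma)) return(breaks)
  thr <- max(undo_sd * sigma, min_effect)
  repeat {
    if (length(breaks) <= 2) break
    means <- vapply(seq_len(length(breaks) - 1), function(b)
      mean(x[(breaks[b] + 1):breaks[b + 1]]), numeric(1))
    dm <- abs(diff(means))
    w <- which.min(dm)
    if (dm[w] >= thr) break
    breaks <- breaks[-(w + 1)]
  }
  breaks
}

# returns absolute break positions (offsets from the start of x) accepted
# by the permutation test
segment_recurse <- function(x, lo, hi, alpha, n_perm) {
  seg <- x[lo:hi]
  bs <- best_split(seg)
  if (is.na(bs[2])) return(integer(0))
  perm_max <- vapply(seq_len(n_perm), function(p)
    best_split(sample(seg))[1], numeric(1))
  pval <- (1 + sum(perm_max >= bs[1])) / (1 + n_perm)
  if (pval >= alpha) return(integer(0))
  k <- lo + bs[2] - 1
  c(segment_recurse(x, lo, k, alpha, n_perm), k,
    segment_recurse(x, k + 1, hi, alpha, n_perm))
}

#' @export
print.SegmentSet <- function(x, ...) {
  s <- x$segments
  cat(sprintf("SegmentSet: %d segments (%d gain, %d loss, %d neutral)\n",
              nrow(s), sum(s$label == "gain", na.rm = TRUE),
              sum(s$label == "loss", na.rm = TRUE),
              sum(s$label == "neutral", na.rm = TRUE)))
  invisible(x)
}
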