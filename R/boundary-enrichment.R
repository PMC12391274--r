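# TAD-boundary ubiquity sets and chromatin-feature enrichment tests.

#' Build boundary ubiquity sets across samples
#'
#' Every boundary of every sample is expanded to `expand` bp about its
#' midpoint; expansions are merged across samples by single linkage
#' (overlapping ranges coalesce); merged ranges of `max_width` or more are
#' discarded. For each surviving range, the ubiquity u counts the samples
#' whose original (unexpanded) boundaries fall inside it. Coordinates are
#' not clipped at chromosome starts, so expansion is symmetric everywhere.
#'
#' @param boundary_sets list of `BoundarySet` objects (one per sample).
#' @param expand expanded boundary width (bp).
#' @param max_width merged ranges at or above this width are discarded.
#' @return data frame with `chrom`, `start`, `end`, `u`.
#' @export
build_ubiquity_sets <- function(boundary_sets, expand = 60000,
                                max_width = 100000) {
  stopifnot(length(boundary_sets) >= 2)
  pools <- lapply(seq_along(boundary_sets), function(s) {
    b <- boundary_sets[[s]]$boundaries
    data.frame(chrom = b$chrom, pos = b$pos, sample = s)
  })
  pool <- do.call(rbind, pools)
  if (nrow(pool) == 0)
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      u = integer()))
  gr <- GenomicRanges::GRanges(pool$chrom,
                               IRanges::IRanges(pool$pos - expand / 2 + 1,
                                                pool$pos + expand / 2))
  merged <- GenomicRanges::reduce(gr)
  keep <- GenomicRanges::width(merged) < max_width
  merged <- merged[keep]
  pts <- GenomicRanges::GRanges(pool$chrom, IRanges::IRanges(pool$pos, pool$pos))
  hits <- GenomicRanges::findOverlaps(pts, merged)
  u <- vapply(seq_along(merged), function(k) {
    length(unique(pool$sample[S4Vectors::queryHits(hits)[
      S4Vectors::subjectHits(hits) == k]]))
  }, integer(1))
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(merged)),
                    start = GenomicRanges::start(merged) - 1,
                    end = GenomicRanges::end(merged), u = u)
  out[out$u >= 1, ]
}

#' Boundary-ubiquity enrichment test per peak dataset
#'
#' For each dataset, each ubiquity level's observed number of boundaries
#' overlapping at least one peak is compared with the expected number (set
#' size times the global per-boundary overlap rate) via the pseudo-counted
#' ratio rho_u = (observed + 1) / (expected + 1). A Gaussian likelihood
#' ratio test compares the linear model rho ~ u against the constant model
#' (2 delta log-likelihood against chi-squared, 1 df); p values are
#' Benjamini-Hochberg adjusted across datasets. A negative slope means the
#' feature associates with sample-specific boundaries, a positive slope
#' with sample-invariant ones.
#'
#' @param ub ubiquity table from [build_ubiquity_sets()].
#' @param peak_sets named list of peak data frames (`chrom`, `start`, `end`).
#' @param fdr significance threshold on the adjusted q value.
#' @return data frame per dataset: `dataset`, `slope`, `lrt`, `p`, `q`,
#'   `significant`, `direction`; attribute `"per_ubiquity"` holds the
#'   observed/expected/rho table per dataset.
#' @export
enrichment_test <- function(ub, peak_sets, fdr = 0.001) {
  if (length(unique(ub$u)) < 3)
    stopf("need at least 3 distinct ubiquity levels (%d present)",
          length(unique(ub$u)))
  bgr <- GenomicRanges::GRanges(ub$chrom, IRanges::IRanges(ub$start + 1, ub$end))
  rows <- list(); per_ub <- list()
  for (ds in names(peak_sets)) {
    pk <- peak_sets[[ds]]
    pk <- pk[pk$chrom %in% unique(ub$chrom), , drop = FALSE]
    if (nrow(pk) == 0) {
      message(sprintf("enrichment_test: dataset %s has no peaks on covered chromosomes; skipped", ds))
      next
    }
    pgr <- GenomicRanges::GRanges(pk$chrom, IRanges::IRanges(pk$start + 1, pk$end))
    hit <- IRanges::overlapsAny(bgr, pgr)
    rate <- mean(hit)
    levels_u <- sort(unique(ub$u))
    obs <- vapply(levels_u, function(l) sum(hit[ub$u == l]), numeric(1))
    n_l <- vapply(levels_u, function(l) sum(ub$u == l), numeric(1))
    expd <- n_l * rate
    rho <- (obs + 1) / (expd + 1)
    df <- data.frame(u = levels_u, n = n_l, observed = obs, expected = expd,
                     rho = rho)
    per_ub[[ds]] <- df
    fit1 <- stats::lm(rho ~ u, data = df)
    fit0 <- stats::lm(rho ~ 1, data = df)
    n <- nrow(df)
    rss0 <- sum(stats::resid(fit0)^2)
    rss1 <- sum(stats::resid(fit1)^2)
    lrt <- if (rss0 < 1e-12) 0 else n * log(rss0 / max(rss1, 1e-12))
    p <- stats::pchisq(lrt, df = 1, lower.tail = FALSE)
    slope <- unname(stats::coef(fit1)[2])
    rows[[ds]] <- data.frame(dataset = ds, slope = slope, lrt = lrt, p = p)
  }
  if (!length(rows)) stopf("no dataset could be tested")
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$q < fdr
  out$direction <- ifelse(out$slope < 0, "sample_specific", "sample_invariant")
  rownames(out) <- NULL
  attr(out, "per_ubiquity") <- per_ub
  out
}
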