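#' Specification of a synthetic Hi-C experiment
#'
#' Defines a small genome and the architectural features to plant in it:
#' power-law distance decay, an A/B checkerboard of tunable strength, TAD
#' blocks with boundaries of tunable depth, copy-number events scaling
#' coverage, translocations producing corner-shaped trans enrichment, and
#' pairwise enrichment between planted anchor clusters. The expectation
#' model is multiplicative — decay x compartment x TAD for cis, a uniform
#' per-pair background plus corner terms for trans — with copy-number
#' events applied as coverage scaling: per-bin diagonal coefficients are
#' solved so that each bin's expected coverage is exactly its planted copy
#' ratio times the CNV-free value. Counts are Poisson (optionally negative binomial)
#' draws from it, so the generator matches the observed/expected
#' decomposition every downstream stage assumes.
#'
#' @param chrom_sizes named numeric vector of chromosome lengths (bp).
#' @param bin_size bin size (bp).
#' @param decay_exponent power-law slope of cis contact frequency vs bin
#'   separation; expectation is proportional to (separation + 1)^-decay_exponent.
#' @param depth total expected read pairs genome-wide.
#' @param seed integer seed; identical specs with identical seeds give
#'   identical output.
#' @param compartments `NULL` for no compartment structure, or a list with
#'   `strength` (s in \[0, 1\]) and either `block_size` (bp; alternating A/B
#'   blocks) or `labels` (named list of per-bin +1/-1 vectors per chromosome).
#' @param tads `NULL`, or a list with either `spacing` (bp between regular
#'   boundaries) and `depth` (d in \[0, 1\]), or `boundaries` (named list of
#'   data frames `bin`, `depth`; `bin` is the 1-based bin index on that
#'   chromosome after which the boundary falls).
#' @param cnv_events `NULL` or data frame `chrom`, `start`, `end`, `ratio`
#'   (copy ratio > 0). Events may not overlap on one chromosome.
#' @param translocations `NULL` or data frame `chromA`, `posA`, `chromB`,
#'   `posB`, `orientation` (one of `"++"`, `"+-"`, `"-+"`, `"--"`). Each row
#'   plants one elevated trans quadrant: `+` selects bins at or after the
#'   breakpoint on that chromosome, `-` bins at or before it. A reciprocal
#'   translocation is two rows with opposite orientations.
#' @param cluster_pairs `NULL` or data frame `chrom1`, `start1`, `end1`,
#'   `chrom2`, `start2`, `end2`, `factor` (enrichment e >= 1); cis
#'   expectation in a square neighbourhood of the anchor-midpoint pixel is
#'   multiplied by e.
#' @param centromeres `NULL` or data frame `chrom`, `start`, `end`.
#' @param trans_level per-pixel trans background relative to the cis base.
#' @param tr_amplitude translocation corner apex height, in multiples of the
#'   trans background; the corner decays as (1 + dx + dy)^-0.5 from the
#'   apex. The default (20, i.e. the reciprocal of `trans_level`) makes the
#'   apex reach cis-level intensity, as expected when two loci become
#'   covalently joined in a clonal rearrangement.
#' @param cluster_radius half-width (bins) of the enriched neighbourhood
#'   around each planted cluster-pair pixel.
#' @param compartment_contrast checkerboard contrast scale: same-label pairs
#'   are multiplied by (1 + s * contrast), cross-label by (1 - s * contrast),
#'   in cis and in trans (A/B segregation is genome-wide).
#' @param boundary_penalty fraction of contacts removed when crossing a
#'   full-depth (d = 1) boundary.
#' @param covariate_bias when `TRUE`, the expectation additionally carries a
#'   per-bin visibility factor derived from the simulated mappability and
#'   restriction-site tracks, so covariate regression has signal to remove.
#' @param overdispersion `NULL` for Poisson counts, or a positive negative
#'   binomial size parameter (smaller = more overdispersed).
#' @return object of class `SyntheticSpec`.
#' @export
synthetic_spec <- function(chrom_sizes, bin_size,
                           decay_exponent = 1, depth = 1e7, seed = 1,
                           compartments = NULL, tads = NULL,
                           cnv_events = NULL, translocations = NULL,
                           cluster_pairs = NULL, centromeres = NULL,
                           trans_level = 0.05, tr_amplitude = 20,
                           cluster_radius = 4,
                           compartment_contrast = 0.6,
                           boundary_penalty = 0.8,
                           covariate_bias = FALSE, overdispersion = NULL) {
  stopifnot(length(chrom_sizes) >= 1, !is.null(names(chrom_sizes)),
            bin_size > 0, depth > 0)
  bins <- bin_table(chrom_sizes, bin_size)
  nb_chr <- table(factor(bins$chrom, levels = names(chrom_sizes)))
  if (max(nb_chr) > 6000)
    stopf("chromosome with %d bins: dense simulation would be too large", max(nb_chr))

  check_interval <- function(chrom, start, end, what) {
    if (!chrom %in% names(chrom_sizes)) stopf("%s: unknown chromosome %s", what, chrom)
    if (start < 0 || end > chrom_sizes[[chrom]] || start >= end)
      stopf("%s: interval [%s, %s) outside %s", what, start, end, chrom)
  }

  labels <- lapply(names(chrom_sizes), function(chr) rep(0, nb_chr[[chr]]))
  names(labels) <- names(chrom_sizes)
  s <- 0
  if (!is.null(compartments)) {
    s <- compartments$strength
    stopifnot(s >= 0, s <= 1)
    if (!is.null(compartments$labels)) {
      for (chr in names(compartments$labels)) {
        l <- compartments$labels[[chr]]
        if (length(l) != nb_chr[[chr]]) stopf("labels for %s have wrong length", chr)
        labels[[chr]] <- sign(l)
      }
    } else {
      bb <- max(1L, round(compartments$block_size / bin_size))
      for (chr in names(chrom_sizes)) {
        n <- nb_chr[[chr]]
        labels[[chr]] <- ifelse((ceiling(seq_len(n) / bb) %% 2) == 1, 1, -1)
      }
    }
  }

  boundaries <- lapply(names(chrom_sizes), function(chr)
    data.frame(bin = integer(), depth = numeric()))
  names(boundaries) <- names(chrom_sizes)
  if (!is.null(tads)) {
    if (!is.null(tads$boundaries)) {
      for (chr in names(tads$boundaries)) {
        b <- as.data.frame(tads$boundaries[[chr]])
        stopifnot(all(b$depth >= 0), all(b$depth <= 1),
                  all(b$bin >= 1), all(b$bin < nb_chr[[chr]]))
        boundaries[[chr]] <- b[order(b$bin), ]
      }
    } else {
      sp <- max(1L, round(tads$spacing / bin_size))
      stopifnot(tads$depth >= 0, tads$depth <= 1)
      for (chr in names(chrom_sizes)) {
        n <- nb_chr[[chr]]
        pos <- seq(sp, n - 1, by = sp)
        boundaries[[chr]] <- data.frame(bin = pos, depth = rep(tads$depth, length(pos)))
      }
    }
  }

  if (!is.null(cnv_events)) {
    cnv_events <- as.data.frame(cnv_events)
    if (any(cnv_events$ratio <= 0)) stopf("copy ratio must be > 0")
    for (k in seq_len(nrow(cnv_events)))
      check_interval(cnv_events$chrom[k], cnv_events$start[k], cnv_events$end[k], "cnv_events")
    for (chr in unique(cnv_events$chrom)) {
      ev <- cnv_events[cnv_events$chrom == chr, ]
      ev <- ev[order(ev$start), ]
      if (nrow(ev) > 1 && any(ev$start[-1] < ev$end[-nrow(ev)]))
        stopf("overlapping CNV events on %s: copy ratio would be ambiguous", chr)
    }
  }
  ratio <- rep(1, nrow(bins))
  event_id <- integer(nrow(bins))
  if (!is.null(cnv_events)) {
    mid <- (bins$start + bins$end) / 2
    for (k in seq_len(nrow(cnv_events))) {
      sel <- bins$chrom == cnv_events$chrom[k] &
        mid >= cnv_events$start[k] & mid < cnv_events$end[k]
      ratio[sel] <- cnv_events$ratio[k]
      event_id[sel] <- k
    }
  }

  if (!is.null(translocations)) {
    translocations <- as.data.frame(translocations)
    stopifnot(all(translocations$orientation %in% c("++", "+-", "-+", "--")))
    for (k in seq_len(nrow(translocations))) {
      check_interval(translocations$chromA[k], translocations$posA[k],
                     translocations$posA[k] + 1, "translocations")
      check_interval(translocations$chromB[k], translocations$posB[k],
                     translocations$posB[k] + 1, "translocations")
      if (translocations$chromA[k] == translocations$chromB[k])
        stopf("translocations must join two different chromosomes")
    }
  }
  if (!is.null(cluster_pairs)) {
    cluster_pairs <- as.data.frame(cluster_pairs)
    if (any(cluster_pairs$factor < 1)) stopf("cluster enrichment factor must be >= 1")
    for (k in seq_len(nrow(cluster_pairs))) {
      check_interval(cluster_pairs$chrom1[k], cluster_pairs$start1[k],
                     cluster_pairs$end1[k], "cluster_pairs")
      check_interval(cluster_pairs$chrom2[k], cluster_pairs$start2[k],
                     cluster_pairs$end2[k], "cluster_pairs")
    }
  }

  structure(list(chrom_sizes = chrom_sizes, bin_size = bin_size,
                 bins = bins, decay_exponent = decay_exponent, depth = depth,
                 seed = seed, strength = s, labels = labels,
                 boundaries = boundaries, cnv_events = cnv_events,
                 ratio = ratio, event_id = event_id,
                 translocations = translocations,
                 cluster_pairs = cluster_pairs, centromeres = centromeres,
                 trans_level = trans_level, tr_amplitude = tr_amplitude,
                 cluster_radius = cluster_radius,
                 compartment_contrast = compartment_contrast,
                 boundary_penalty = boundary_penalty,
                 covariate_bias = covariate_bias,
                 overdispersion = overdispersion),
            class = "SyntheticSpec")
}

#' @export
print.SyntheticSpec <- function(x, ...) {
  cat(sprintf("SyntheticSpec: %d chromosome(s), %s bp bins, depth %s, seed %d\n",
              length(x$chrom_sizes), format(x$bin_size, big.mark = ","),
              format(x$depth, big.mark = ","), x$seed))
  cat(sprintf("  compartment strength %.2f; %d TAD boundaries; %d CNV events; %d translocations; %d cluster pairs\n",
              x$strength, sum(vapply(x$boundaries, nrow, 1L)),
              if (is.null(x$cnv_events)) 0L else nrow(x$cnv_events),
              if (is.null(x$translocations)) 0L else nrow(x$translocations),
              if (is.null(x$cluster_pairs)) 0L else nrow(x$cluster_pairs)))
  invisible(x)
}

# bin index (1-based, within chromosome) of a bp position
pos_to_bin <- function(spec, pos) floor(pos / spec$bin_size) + 1L

# per-bin visibility factor from the covariate tracks (1 everywhere when
# covariate_bias is off)
visibility <- function(spec) {
  if (!spec$covariate_bias) return(rep(1, nrow(spec$bins)))
  tr <- simulate_tracks(spec)
  tr$mappability * (tr$sites / mean(tr$sites))^0.7
}

#' Analytic expectation of the generative model
#'
#' Dense per-pixel expected counts for one chromosome pair, before Poisson
#' sampling. This is the oracle the generator's own output is tested
#' against; [simulate_matrix()] draws counts from exactly these values.
#'
#' @param spec a `SyntheticSpec`.
#' @param chromA,chromB chromosome names (`chromB = chromA` for cis).
#' @param scaled when `TRUE` (default) values are scaled so that the
#'   genome-wide expectation sums to `spec$depth`; when `FALSE` the
#'   unnormalised relative expectation is returned.
#' @return dense numeric matrix of expected counts.
#' @export
synthetic_expectation <- function(spec, chromA, chromB = chromA, scaled = TRUE) {
  e <- expectation_raw(spec, chromA, chromB)
  if (scaled) e <- e * expectation_scale(spec)
  e
}

expectation_raw <- function(spec, chromA, chromB, coef = NULL) {
  bins <- spec$bins
  ia <- which(bins$chrom == chromA)
  ib <- which(bins$chrom == chromB)
  if (!length(ia) || !length(ib)) stopf("unknown chromosome")
  v <- visibility(spec)
  na <- length(ia); nb <- length(ib)
  if (chromA == chromB) {
    d <- abs(outer(seq_len(na), seq_len(na), "-"))
    e <- (d + 1)^(-spec$decay_exponent)
    l <- spec$labels[[chromA]]
    if (spec$strength > 0 && any(l != 0))
      e <- e * (1 + spec$strength * spec$compartment_contrast * outer(l, l))
    bd <- spec$boundaries[[chromA]]
    if (nrow(bd) > 0) {
      # pen[b] = log of the crossing penalty of the boundary after bin b;
      # contacts (i, j) cross every boundary after bins i .. j-1, so the
      # joint penalty is exp(S[j] - S[i]) with S the cumulative sum.
      pen <- numeric(na)
      pen[bd$bin] <- log(1 - spec$boundary_penalty * bd$depth)
      S <- c(0, cumsum(pen))[seq_len(na)]  # S[i] = penalties after bins 1..i-1
      e <- e * exp(-abs(outer(S, S, "-")))
    }
    if (!is.null(spec$cluster_pairs)) {
      cp <- spec$cluster_pairs
      r <- spec$cluster_radius
      for (k in seq_len(nrow(cp))) {
        if (cp$chrom1[k] != chromA || cp$chrom2[k] != chromA) next
        b1 <- pos_to_bin(spec, (cp$start1[k] + cp$end1[k]) / 2)
        b2 <- pos_to_bin(spec, (cp$start2[k] + cp$end2[k]) / 2)
        w1 <- max(1, b1 - r):min(na, b1 + r)
        w2 <- max(1, b2 - r):min(na, b2 + r)
        e[w1, w2] <- e[w1, w2] * cp$factor[k]
        e[w2, w1] <- e[w2, w1] * cp$factor[k]
      }
    }
    e <- e * outer(v[ia], v[ia])
  } else {
    e <- matrix(spec$trans_level, na, nb)
    la <- spec$labels[[chromA]]; lb <- spec$labels[[chromB]]
    if (spec$strength > 0 && (any(la != 0) || any(lb != 0)))
      e <- e * (1 + spec$strength * spec$compartment_contrast * outer(la, lb))
    if (!is.null(spec$translocations)) {
      tl <- spec$translocations
      for (k in seq_len(nrow(tl))) {
        swap <- tl$chromA[k] == chromB && tl$chromB[k] == chromA
        if (!(tl$chromA[k] == chromA && tl$chromB[k] == chromB) && !swap) next
        oa <- substr(tl$orientation[k], 1, 1)
        ob <- substr(tl$orientation[k], 2, 2)
        if (swap) { tmp <- oa; oa <- ob; ob <- tmp }
        ba <- pos_to_bin(spec, if (swap) tl$posB[k] else tl$posA[k])
        bb <- pos_to_bin(spec, if (swap) tl$posA[k] else tl$posB[k])
        da <- if (oa == "+") pmax(seq_len(na) - ba, -1) else pmax(ba - seq_len(na), -1)
        db <- if (ob == "+") pmax(seq_len(nb) - bb, -1) else pmax(bb - seq_len(nb), -1)
        inA <- da >= 0; inB <- db >= 0
        corner <- matrix(0, na, nb)
        if (any(inA) && any(inB)) {
          dd <- outer(da[inA], db[inB], "+")
          corner[inA, inB] <- spec$tr_amplitude * (1 + dd)^(-0.5)
        }
        e <- e + spec$trans_level * corner
      }
    }
    e <- e * outer(v[ia], v[ib])
  }
  if (is.null(coef)) coef <- cnv_coef(spec)
  e * outer(coef[ia], coef[ib])
}

# structural expectation only (decay, compartments, TADs, clusters, corners,
# visibility) without copy-number scaling
expectation_structural <- function(spec, chromA, chromB)
  expectation_raw(spec, chromA, chromB, coef = rep(1, nrow(spec$bins)))

# Diagonal scaling implementing copy-number events as coverage scaling:
# per-bin coefficients c such that the marginal (both-mate coverage) of the
# scaled expectation c_i c_j E0_ij equals ratio_i times the CNV-free
# marginal. Solved by a damped Sinkhorn iteration on the structural
# expectation; all-neutral genomes return unit coefficients.
cnv_coef <- function(spec) {
  r <- spec$ratio
  n <- length(r)
  if (all(r == 1)) return(rep(1, n))
  chroms <- names(spec$chrom_sizes)
  idx <- lapply(chroms, function(ch) which(spec$bins$chrom == ch))
  blocks <- list()
  for (a in seq_along(chroms)) for (b in a:length(chroms))
    blocks[[length(blocks) + 1L]] <- list(
      ia = idx[[a]], ib = idx[[b]],
      e = expectation_structural(spec, chroms[a], chroms[b]))
  marg <- function(coef) {
    m <- numeric(n)
    for (bl in blocks) {
      if (identical(bl$ia, bl$ib)) {
        v <- drop(bl$e %*% coef[bl$ia])
        m[bl$ia] <- m[bl$ia] + coef[bl$ia] * v + coef[bl$ia]^2 * diag(bl$e)
      } else {
        m[bl$ia] <- m[bl$ia] + coef[bl$ia] * drop(bl$e %*% coef[bl$ib])
        m[bl$ib] <- m[bl$ib] + coef[bl$ib] * drop(crossprod(bl$e, coef[bl$ia]))
      }
    }
    m
  }
  target <- r * marg(rep(1, n))
  coef <- r
  for (it in 1:100) {
    m <- marg(coef)
    if (max(abs(m / target - 1)) < 1e-10) break
    coef <- coef * sqrt(target / m)
  }
  coef
}

expectation_scale <- function(spec, coef = NULL) {
  if (is.null(coef)) coef <- cnv_coef(spec)
  chroms <- names(spec$chrom_sizes)
  total <- 0
  for (a in seq_along(chroms)) {
    ec <- expectation_raw(spec, chroms[a], chroms[a], coef = coef)
    total <- total + (sum(ec) + sum(diag(ec))) / 2
    if (a < length(chroms)) for (b in (a + 1):length(chroms))
      total <- total + sum(expectation_raw(spec, chroms[a], chroms[b], coef = coef))
  }
  spec$depth / total
}

#' Simulate a Hi-C contact matrix with planted ground truth
#'
#' Draws Poisson (or negative binomial, if `spec$overdispersion` is set)
#' counts from the generative expectation and assembles them into a sparse
#' `ContactMatrix`. Identical specs and seeds yield identical matrices.
#'
#' @param spec a `SyntheticSpec`.
#' @return list with `matrix` (a `ContactMatrix`) and `truth`, a record of
#'   every planted feature in bin coordinates: `labels` (per-bin A/B as
#'   +1/-1/0), `boundaries` (per-chromosome bin indices and depths), `ratio`
#'   (per-bin copy ratio), `translocations` and `cluster_pairs` with bin
#'   columns added.
#' @export
simulate_matrix <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  chroms <- names(spec$chrom_sizes)
  coef <- cnv_coef(spec)
  sc <- expectation_scale(spec, coef = coef)
  offs <- c(0, cumsum(vapply(chroms, function(ch) sum(spec$bins$chrom == ch), 1)))
  names(offs) <- c(chroms, "end")
  draw <- function(lam) {
    if (is.null(spec$overdispersion)) stats::rpois(length(lam), lam)
    else stats::rnbinom(length(lam), mu = lam, size = spec$overdispersion)
  }
  px <- with_seed(spec$seed, {
    out <- list()
    for (a in seq_along(chroms)) {
      lam <- expectation_raw(spec, chroms[a], chroms[a], coef = coef) * sc
      n <- nrow(lam)
      ut <- which(upper.tri(lam, diag = TRUE))
      cnt <- draw(lam[ut])
      keep <- cnt > 0
      ij <- arrayInd(ut[keep], dim(lam))
      out[[length(out) + 1L]] <- data.frame(
        bin1 = ij[, 1] + offs[[a]], bin2 = ij[, 2] + offs[[a]], count = cnt[keep])
      if (a < length(chroms)) for (b in (a + 1):length(chroms)) {
        lam <- expectation_raw(spec, chroms[a], chroms[b], coef = coef) * sc
        cnt <- draw(lam)
        keep <- cnt > 0
        ij <- arrayInd(which(keep), dim(lam))
        out[[length(out) + 1L]] <- data.frame(
          bin1 = ij[, 1] + offs[[a]], bin2 = ij[, 2] + offs[[b]], count = cnt[keep])
      }
    }
    do.call(rbind, out)
  })
  m <- contact_matrix(spec$bins, px, resolution = spec$bin_size)
  truth <- list(labels = spec$labels, boundaries = spec$boundaries,
                ratio = spec$ratio, cnv_events = spec$cnv_events,
                translocations = if (!is.null(spec$translocations)) {
                  tl <- spec$translocations
                  tl$binA <- pos_to_bin(spec, tl$posA)
                  tl$binB <- pos_to_bin(spec, tl$posB)
                  tl
                },
                cluster_pairs = if (!is.null(spec$cluster_pairs)) {
                  cp <- spec$cluster_pairs
                  cp$bin1 <- pos_to_bin(spec, (cp$start1 + cp$end1) / 2)
                  cp$bin2 <- pos_to_bin(spec, (cp$start2 + cp$end2) / 2)
                  cp
                })
  list(matrix = m, truth = truth)
}

#' Simulate bin-annotation covariate tracks
#'
#' GC fraction is constructed to be higher in planted A-compartment bins (so
#' GC-based eigenvector signing is testable), mappability lies in (0, 1],
#' and restriction-site counts are positive integers with mean proportional
#' to bin size (one site per ~256 bp, the density of a 4-base cutter).
#' Deterministic given the spec seed.
#'
#' @param spec a `SyntheticSpec`.
#' @return data frame with one row per bin: `chrom`, `start`, `end`, `gc`,
#'   `mappability`, `sites`.
#' @export
simulate_tracks <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  n <- nrow(spec$bins)
  l <- unlist(spec$labels[unique(spec$bins$chrom)], use.names = FALSE)
  with_seed(child_seed(spec$seed, 2), {
    gc <- 0.41 + 0.04 * l + stats::rnorm(n, 0, 0.01)
    gc <- pmin(0.8, pmax(0.2, gc))
    mapp <- stats::rbeta(n, 20, 2)
    mapp <- pmin(1, pmax(1e-3, mapp))
    sites <- stats::rpois(n, (spec$bins$end - spec$bins$start) / 256) + 1L
    data.frame(chrom = spec$bins$chrom, start = spec$bins$start,
               end = spec$bins$end, gc = gc, mappability = mapp, sites = sites)
  })
}

#' Simulate transcription-factor binding peaks
#'
#' Emits BED-style peaks with dense clusters placed at the midpoints of the
#' spec's `cluster_pairs` anchors (so cluster-pair pile-up ground truth is
#' aligned), plus optional additional clusters and isolated background peaks
#' at seeded random positions.
#'
#' @param spec a `SyntheticSpec`.
#' @param n_clusters total number of clusters to emit; defaults to the
#'   number of distinct anchors. Extra clusters beyond the anchors are
#'   placed at random. `0` yields only background peaks.
#' @param peaks_per_cluster peaks per cluster.
#' @param gap distance between successive peak midpoints within a cluster
#'   (bp); must be < 20000 for clusters to satisfy the downstream
#'   >= 3-peaks-within-20-kb rule.
#' @param peak_width width of each peak (bp).
#' @param background_peaks number of isolated random peaks to add.
#' @return data frame with `chrom`, `start`, `end`, `name`.
#' @export
simulate_peaks <- function(spec, n_clusters = NULL, peaks_per_cluster = 3,
                           gap = 15000, peak_width = 500,
                           background_peaks = 0) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  anchors <- list()
  if (!is.null(spec$cluster_pairs)) {
    cp <- spec$cluster_pairs
    for (k in seq_len(nrow(cp))) {
      anchors[[length(anchors) + 1L]] <- list(chrom = cp$chrom1[k],
                                              mid = (cp$start1[k] + cp$end1[k]) / 2)
      anchors[[length(anchors) + 1L]] <- list(chrom = cp$chrom2[k],
                                              mid = (cp$start2[k] + cp$end2[k]) / 2)
    }
    key <- vapply(anchors, function(a) paste(a$chrom, a$mid), "")
    anchors <- anchors[!duplicated(key)]
  }
  if (is.null(n_clusters)) n_clusters <- length(anchors)
  with_seed(child_seed(spec$seed, 3), {
    while (length(anchors) < n_clusters) {
      chr <- sample(names(spec$chrom_sizes), 1)
      anchors[[length(anchors) + 1L]] <-
        list(chrom = chr, mid = stats::runif(1, 1e5, spec$chrom_sizes[[chr]] - 1e5))
    }
    anchors <- anchors[seq_len(n_clusters)]
    rows <- list()
    for (a in anchors) {
      span <- (peaks_per_cluster - 1) * gap
      starts <- round(a$mid - span / 2 + (seq_len(peaks_per_cluster) - 1) * gap -
                        peak_width / 2)
      if (any(starts < 0) || any(starts + peak_width > spec$chrom_sizes[[a$chrom]]))
        stopf("cluster peaks extend past the end of %s", a$chrom)
      rows[[length(rows) + 1L]] <- data.frame(chrom = a$chrom, start = starts,
                                              end = starts + peak_width)
    }
    for (k in seq_len(background_peaks)) {
      chr <- sample(names(spec$chrom_sizes), 1)
      st <- round(stats::runif(1, 0, spec$chrom_sizes[[chr]] - peak_width))
      rows[[length(rows) + 1L]] <- data.frame(chrom = chr, start = st,
                                              end = st + peak_width)
    }
    if (!length(rows))
      return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                        name = character()))
    out <- do.call(rbind, rows)
    out <- out[order(out$chrom, out$start), ]
    out$name <- paste0("peak_", seq_len(nrow(out)))
    rownames(out) <- NULL
    out
  })
}

#' Write the planted ground truth as a JSON sidecar
#' @param truth the `truth` component of [simulate_matrix()] output.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
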