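#' Binned Hi-C contact matrix
#'
#' A sparse, genome-wide binned contact matrix: an ordered bin table tiling
#' each chromosome at uniform resolution (the last bin of a chromosome may be
#' short), upper-triangular pixel triplets of raw counts, and optional
#' per-bin balancing weights. Coordinates are 0-based half-open; pixel bin
#' ids are 1-based row indices into the bin table, with `bin1 <= bin2`.
#'
#' @param bins data frame with `chrom`, `start`, `end`.
#' @param pixels data frame with `bin1`, `bin2`, `count` (non-negative
#'   integers). Lower-triangular triplets are flipped to the upper triangle;
#'   duplicate triplets are summed.
#' @param resolution bin size in bp.
#' @param weights optional numeric vector of balancing weights (NA = masked).
#' @return an object of class `ContactMatrix`.
#' @export
contact_matrix <- function(bins, pixels, resolution, weights = NULL) {
  bins <- as.data.frame(bins)[, c("chrom", "start", "end")]
  bins$chrom <- as.character(bins$chrom)
  pixels <- as.data.frame(pixels)[, c("bin1", "bin2", "count")]
  validate_bins(bins, resolution)
  if (any(pixels$count < 0)) stopf("negative counts in pixel table")
  if (any(pixels$count != round(pixels$count)))
    stopf("raw counts must be integers")
  if (any(pixels$bin1 < 1 | pixels$bin2 < 1 |
          pixels$bin1 > nrow(bins) | pixels$bin2 > nrow(bins)))
    stopf("pixel bin ids outside bin table")
  flip <- pixels$bin1 > pixels$bin2
  if (any(flip)) {
    tmp <- pixels$bin1[flip]
    pixels$bin1[flip] <- pixels$bin2[flip]
    pixels$bin2[flip] <- tmp
  }
  # collapse duplicates (can arise from flipping)
  key <- paste(pixels$bin1, pixels$bin2)
  if (anyDuplicated(key)) {
    agg <- rowsum(pixels$count, key)
    ij <- do.call(rbind, strsplit(rownames(agg), " ", fixed = TRUE))
    pixels <- data.frame(bin1 = as.integer(ij[, 1]), bin2 = as.integer(ij[, 2]),
                         count = as.numeric(agg))
  }
  pixels <- pixels[order(pixels$bin1, pixels$bin2), , drop = FALSE]
  rownames(pixels) <- NULL
  if (!is.null(weights) && length(weights) != nrow(bins))
    stopf("weights length (%d) != number of bins (%d)", length(weights), nrow(bins))
  structure(list(bins = bins, pixels = pixels, resolution = resolution,
                 weights = weights),
            class = "ContactMatrix")
}

validate_bins <- function(bins, resolution) {
  for (chr in unique(bins$chrom)) {
    b <- bins[bins$chrom == chr, ]
    if (b$start[1] != 0) stopf("bins of %s do not start at 0", chr)
    if (nrow(b) > 1) {
      if (any(b$start[-1] != b$end[-nrow(b)]))
        stopf("bins of %s have gaps or overlaps", chr)
      if (any(b$end[-nrow(b)] - b$start[-nrow(b)] != resolution))
        stopf("non-uniform bins on %s (only the last bin may be short)", chr)
    }
    if (b$end[nrow(b)] - b$start[nrow(b)] > resolution)
      stopf("last bin of %s exceeds resolution", chr)
  }
  invisible(TRUE)
}

#' Build a uniform bin table for a genome
#' @param chrom_sizes named numeric vector of chromosome lengths (bp).
#' @param bin_size bin size in bp.
#' @return data frame with `chrom`, `start`, `end`.
#' @export
bin_table <- function(chrom_sizes, bin_size) {
  out <- lapply(names(chrom_sizes), function(chr) {
    starts <- seq(0, chrom_sizes[[chr]] - 1, by = bin_size)
    data.frame(chrom = chr, start = starts,
               end = pmin(starts + bin_size, chrom_sizes[[chr]]))
  })
  do.call(rbind, out)
}

#' @export
print.ContactMatrix <- function(x, ...) {
  nchr <- length(unique(x$bins$chrom))
  cat(sprintf("ContactMatrix: %d bins on %d chromosome(s) at %s bp\n",
              nrow(x$bins), nchr, format(x$resolution, big.mark = ",")))
  cat(sprintf("  %d non-zero pixels, %s total counts\n",
              nrow(x$pixels), format(sum(x$pixels$count), big.mark = ",")))
  cat(sprintf("  weights: %s\n",
              if (is.null(x$weights)) "absent"
              else sprintf("present (%d masked bins)", sum(is.na(x$weights)))))
  invisible(x)
}

#' @export
summary.ContactMatrix <- function(object, ...) {
  cov <- marginals(object)
  print(object)
  cat("  per-bin coverage (both mates): ")
  print(stats::quantile(cov, c(0, .25, .5, .75, 1)))
  invisible(object)
}

# Chromosome index helpers -------------------------------------------------

chrom_bins <- function(m, chrom) which(m$bins$chrom == chrom)

n_bins <- function(m, chrom) sum(m$bins$chrom == chrom)

# Assign each pixel a cis/trans flag and chromosome labels.
pixel_chroms <- function(m) {
  data.frame(chrom1 = m$bins$chrom[m$pixels$bin1],
             chrom2 = m$bins$chrom[m$pixels$bin2])
}

#' Per-bin genome-wide coverage
#'
#' Counts both mates of every pair: a pixel (i, j) contributes its count to
#' bin i and to bin j, so a diagonal pixel contributes twice to its bin.
#' This is the 5'-end counting used for coverage-based copy-number work.
#'
#' @param m a `ContactMatrix`.
#' @return numeric vector, one value per bin.
#' @export
marginals <- function(m) {
  n <- nrow(m$bins)
  cov <- numeric(n)
  t1 <- rowsum(m$pixels$count, m$pixels$bin1)
  t2 <- rowsum(m$pixels$count, m$pixels$bin2)
  cov[as.integer(rownames(t1))] <- cov[as.integer(rownames(t1))] + t1[, 1]
  cov[as.integer(rownames(t2))] <- cov[as.integer(rownames(t2))] + t2[, 1]
  cov
}

# Balanced pixel values (count * w_i * w_j); NA where either weight missing.
balanced_values <- function(m) {
  if (is.null(m$weights)) stopf("matrix has no balancing weights; run balance() first")
  m$pixels$count * m$weights[m$pixels$bin1] * m$weights[m$pixels$bin2]
}

#' Extract a dense sub-matrix for one chromosome (pair)
#'
#' @param m a `ContactMatrix`.
#' @param chromA,chromB chromosome names; `chromB` defaults to `chromA`
#'   (cis, symmetric dense output).
#' @param what `"count"` for raw counts or `"balanced"` for
#'   weight-corrected values (NA at masked bins).
#' @return dense numeric matrix (`length(chromA bins)` x `length(chromB bins)`).
#' @export
as_dense <- function(m, chromA, chromB = chromA, what = c("count", "balanced")) {
  what <- match.arg(what)
  ia <- chrom_bins(m, chromA)
  ib <- chrom_bins(m, chromB)
  if (!length(ia) || !length(ib)) stopf("unknown chromosome")
  val <- if (what == "balanced") balanced_values(m) else m$pixels$count
  out <- matrix(0, length(ia), length(ib))
  sel <- m$bins$chrom[m$pixels$bin1] == chromA & m$bins$chrom[m$pixels$bin2] == chromB
  if (any(sel)) {
    r <- m$pixels$bin1[sel] - ia[1] + 1L
    c <- m$pixels$bin2[sel] - ib[1] + 1L
    out[cbind(r, c)] <- val[sel]
    if (chromA == chromB) out[cbind(c, r)] <- val[sel]
  }
  if (chromA != chromB) {
    # pixels stored with bin1 <= bin2 may carry this pair in the other order
    sel2 <- m$bins$chrom[m$pixels$bin1] == chromB & m$bins$chrom[m$pixels$bin2] == chromA
    if (any(sel2)) {
      r <- m$pixels$bin2[sel2] - ia[1] + 1L
      c <- m$pixels$bin1[sel2] - ib[1] + 1L
      out[cbind(r, c)] <- val[sel2]
    }
  }
  if (what == "balanced") {
    out[is.na(m$weights[ia]), ] <- NA
    out[, is.na(m$weights[ib])] <- NA
  }
  out
}

# I/O ----------------------------------------------------------------------

#' Write a contact matrix as COO text + bin table
#'
#' Layout mirrors a cooler dump: `<prefix>.bins.tsv` holds `chrom`, `start`,
#' `end` (0-based half-open) and, when present, `weight`;
#' `<prefix>.pixels.tsv` holds `bin1_id`, `bin2_id`, `count` with 0-based bin
#' ids into the bin table.
#'
#' @param m a `ContactMatrix`.
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_matrix <- function(m, prefix) {
  bins <- m$bins
  if (!is.null(m$weights)) bins$weight <- m$weights
  utils::write.table(bins, paste0(prefix, ".bins.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  px <- data.frame(bin1_id = m$pixels$bin1 - 1L, bin2_id = m$pixels$bin2 - 1L,
                   count = m$pixels$count)
  utils::write.table(px, paste0(prefix, ".pixels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(prefix)
}

#' Read a contact matrix from COO text + bin table
#'
#' @param prefix path prefix as used by [write_matrix()].
#' @param resolution bin size in bp; inferred from the bin table when `NULL`.
#' @return a `ContactMatrix`.
#' @export
read_matrix <- function(prefix, resolution = NULL) {
  bins <- utils::read.table(paste0(prefix, ".bins.tsv"), sep = "\t",
                            header = TRUE, colClasses = NA)
  bins$chrom <- as.character(bins$chrom)
  px <- utils::read.table(paste0(prefix, ".pixels.tsv"), sep = "\t", header = TRUE)
  if (is.null(resolution))
    resolution <- max(bins$end - bins$start)
  weights <- if ("weight" %in% names(bins)) bins$weight else NULL
  contact_matrix(bins[, c("chrom", "start", "end")],
                 data.frame(bin1 = px$bin1_id + 1L, bin2 = px$bin2_id + 1L,
                            count = px$count),
                 resolution = resolution, weights = weights)
}
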