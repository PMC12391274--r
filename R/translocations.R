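# Translocation candidate detection in trans matrices: bin filtering,
# NB-GLM copy-number normalisation, compartment (rank-1) removal, median
# filtering, corner convolution, binarisation/dilation, candidate export.

#' Extract and filter a raw trans image
#'
#' Dense raw counts for one chromosome pair; 1D bins with at most
#' `min_bin_reads` genome-wide reads are removed (cis pixels do not enter a
#' trans image by construction).
#'
#' @param m a `ContactMatrix` with raw counts (typically at 500 kb).
#' @param chromA,chromB two different chromosome names.
#' @param min_bin_reads bins must exceed this genome-wide read count.
#' @return object of class `TransImage`: `mat` (current stage), `raw`
#'   (filtered raw counts), `rows`/`cols` (global bin indices), `chromA`,
#'   `chromB`, `stage`.
#' @export
trans_image <- function(m, chromA, chromB, min_bin_reads = 2000) {
  stopifnot(chromA != chromB)
  cov <- marginals(m)
  ia <- chrom_bins(m, chromA)
  ib <- chrom_bins(m, chromB)
  keep_a <- ia[cov[ia] > min_bin_reads]
  keep_b <- ib[cov[ib] > min_bin_reads]
  full <- as_dense(m, chromA, chromB, what = "count")
  mat <- full[keep_a - ia[1] + 1L, keep_b - ib[1] + 1L, drop = FALSE]
  structure(list(mat = mat, raw = mat, rows = keep_a, cols = keep_b,
                 chromA = chromA, chromB = chromB, stage = "raw",
                 bins = m$bins, resolution = m$resolution),
            class = "TransImage")
}

#' @export
print.TransImage <- function(x, ...) {
  cat(sprintf("TransImage %s x %s: %d x %d bins (stage: %s)\n",
              x$chromA, x$chromB, nrow(x$mat), ncol(x$mat), x$stage))
  invisible(x)
}

#' Copy-number normalisation of a trans image (NB-GLM)
#'
#' Fits a negative binomial GLM of the per-cell count on the product of the
#' log10-transformed row and column means, over a seeded random subset of
#' cells, and converts the image to
#' log2((observed + phi) / (expected + phi)) with the model prediction as
#' expected value. Falls back to a quasi-Poisson fit when the NB fit does
#' not converge.
#'
#' @param img a `TransImage` at stage `"raw"`.
#' @param phi pseudo-count.
#' @param subset number of cells used to fit the model.
#' @param seed RNG seed for the cell subset.
#' @return the image at stage `"cnv_normalised"`.
#' @export
cnv_normalise_trans <- function(img, phi = 20, subset = 1e5, seed = 1) {
  mat <- img$mat
  rm_ <- rowMeans(mat); cm_ <- colMeans(mat)
  keep_r <- rm_ > 0; keep_c <- cm_ > 0
  mat <- mat[keep_r, keep_c, drop = FALSE]
  img$raw <- img$raw[keep_r, keep_c, drop = FALSE]
  img$rows <- img$rows[keep_r]; img$cols <- img$cols[keep_c]
  if (nrow(mat) < 2 || ncol(mat) < 2) {
    img$mat <- matrix(numeric(0), 0, 0)
    img$stage <- "cnv_normalised"
    return(img)
  }
  x <- outer(log10(rowMeans(mat)), log10(colMeans(mat)))
  y <- as.vector(mat)
  xv <- as.vector(x)
  n <- length(y)
  sel <- with_seed(seed, sample.int(n, min(subset, n)))
  df <- data.frame(y = y[sel], x = xv[sel])
  fit <- tryCatch(
    suppressWarnings(MASS::glm.nb(y ~ x, data = df)),
    error = function(e) NULL)
  if (is.null(fit) || !fit$converged) {
    message("cnv_normalise_trans: NB fit did not converge; quasi-Poisson fallback")
    fit <- stats::glm(y ~ x, family = stats::quasipoisson(), data = df)
  }
  expected <- as.numeric(stats::predict(fit, newdata = data.frame(x = xv),
                                        type = "response"))
  img$mat <- matrix(log2((y + phi) / (expected + phi)), nrow(mat), ncol(mat))
  img$stage <- "cnv_normalised"
  img
}

#' Compartment normalisation of a trans image (rank-1 removal)
#'
#' The leading singular pair of the CNV-normalised image (the rank-1 term a
#' symmetric eigendecomposition of its two-block embedding yields) forms a
#' predictor — the outer product of the two vectors — which is regressed
#' out with a robust linear fit without intercept; the residual image is
#' returned. A degenerate (rank-0) image is returned unchanged.
#'
#' @param img a `TransImage` at stage `"cnv_normalised"`.
#' @return the image at stage `"residual"`.
#' @export
compartment_normalise <- function(img) {
  mat <- img$mat
  if (length(mat) == 0 || min(dim(mat)) < 2) {
    img$stage <- "residual"
    return(img)
  }
  sv <- tryCatch(svd(mat, nu = 1, nv = 1), error = function(e) NULL)
  if (is.null(sv) || sv$d[1] < 1e-12) {
    message("compartment_normalise: degenerate image; returned unchanged")
    img$stage <- "residual"
    return(img)
  }
  pred <- as.vector(outer(sv$u[, 1], sv$v[, 1]))
  y <- as.vector(mat)
  fit <- tryCatch(
    suppressWarnings(MASS::rlm(y ~ pred + 0, maxit = 50)),
    error = function(e) NULL)
  coefficient <- if (is.null(fit)) sv$d[1] else unname(stats::coef(fit)[1])
  img$mat <- matrix(y - coefficient * pred, nrow(mat), ncol(mat))
  img$stage <- "residual"
  img
}

# 3x3 median filter with replicated borders
median_filter3 <- function(mat) {
  n <- nrow(mat); m <- ncol(mat)
  pad <- matrix(0, n + 2, m + 2)
  pad[2:(n + 1), 2:(m + 1)] <- mat
  pad[1, ] <- pad[2, ]; pad[n + 2, ] <- pad[n + 1, ]
  pad[, 1] <- pad[, 2]; pad[, m + 2] <- pad[, m + 1]
  shifts <- array(NA_real_, dim = c(n, m, 9))
  k <- 0
  for (di in 0:2) for (dj in 0:2) {
    k <- k + 1
    shifts[, , k] <- pad[(1 + di):(n + di), (1 + dj):(m + dj)]
  }
  apply(shifts, c(1, 2), stats::median)
}

# 7x7 zero-sum corner kernel: +1 over one quadrant including the centre
# row/column, the remaining cells scaled negative so the kernel sums to 0
corner_kernel <- function(size = 7, orientation = c("++", "+-", "-+", "--")) {
  orientation <- match.arg(orientation)
  c0 <- (size + 1) / 2
  q <- c0:size
  if (substr(orientation, 1, 1) == "-") q_r <- 1:c0 else q_r <- q
  if (substr(orientation, 2, 2) == "-") q_c <- 1:c0 else q_c <- q
  k <- matrix(0, size, size)
  k[q_r, q_c] <- 1
  npos <- sum(k)
  k[k == 0] <- -npos / (size^2 - npos)
  k
}

#' Corner-response transform of a trans image
#'
#' The residual image is passed through a 3x3 median filter (replicated
#' borders), convolved with a 7x7 zero-sum corner kernel in each of 4
#' orientations, each response floored at `floor` to eliminate anti-pattern
#' values, and the 4 floored responses summed. The kernel is multiplied by
#' `gain`, which couples the response scale to the downstream binarisation
#' threshold.
#'
#' @param img a `TransImage` at stage `"residual"`.
#' @param kernel_size corner kernel size (odd).
#' @param floor_value per-orientation floor.
#' @param gain kernel scaling.
#' @return the image at stage `"corner_response"`.
#' @export
corner_response <- function(img, kernel_size = 7, floor_value = 1, gain = 10) {
  mat <- img$mat
  if (length(mat) == 0 || min(dim(mat)) < kernel_size) {
    message(sprintf("corner_response: image %s x %s smaller than kernel; skipped",
                    img$chromA, img$chromB))
    img$mat <- matrix(numeric(0), 0, 0)
    img$stage <- "corner_response"
    return(img)
  }
  med <- median_filter3(mat)
  resp <- matrix(0, nrow(mat), ncol(mat))
  for (o in c("++", "+-", "-+", "--")) {
    k <- corner_kernel(kernel_size, o) * gain
    r <- EBImage::filter2(med, k, boundary = "replicate")
    resp <- resp + pmax(r, floor_value)
  }
  img$mat <- resp
  img$stage <- "corner_response"
  img
}

# 8-connected component labelling of a logical matrix (flood fill)
label_components <- function(mask) {
  n <- nrow(mask); m <- ncol(mask)
  lab <- matrix(0L, n, m)
  cur <- 0L
  todo <- which(mask)
  for (start in todo) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      px <- queue[length(queue)]
      queue <- queue[-length(queue)]
      i <- (px - 1L) %% n + 1L
      j <- (px - 1L) %/% n + 1L
      for (di in -1:1) for (dj in -1:1) {
        ii <- i + di; jj <- j + dj
        if (ii < 1 || ii > n || jj < 1 || jj > m) next
        q <- (jj - 1L) * n + ii
        if (mask[q] && lab[q] == 0L) {
          lab[q] <- cur
          queue <- c(queue, q)
        }
      }
    }
  }
  lab
}

#' Extract breakpoint candidates from a corner-response image
#'
#' The response is binarised at `binarise`, dilated with a square brush to
#' merge adjacent areas, and 8-connected components are labelled. Within
#' each component the pixel with the highest original raw count becomes the
#' candidate breakpoint.
#'
#' @param img a `TransImage` at stage `"corner_response"` (its `raw` slot
#'   holds the filtered raw counts).
#' @param binarise response threshold.
#' @param brush dilation brush size (odd).
#' @return data frame of `BreakpointCandidate` rows: `chromA`, `posA`,
#'   `chromB`, `posB`, `binA`, `binB` (global bin ids), `corner_response`,
#'   `raw_count`, `area_id`; zero rows when nothing exceeds the threshold.
#' @export
find_candidates <- function(img, binarise = 100, brush = 21) {
  empty <- data.frame(chromA = character(), posA = numeric(),
                      chromB = character(), posB = numeric(),
                      binA = integer(), binB = integer(),
                      corner_response = numeric(), raw_count = numeric(),
                      area_id = integer())
  if (length(img$mat) == 0) return(empty)
  mask <- img$mat > binarise
  if (!any(mask)) return(empty)
  dil <- EBImage::dilate(mask + 0, EBImage::makeBrush(brush, "box")) > 0
  lab <- label_components(dil)
  out <- list()
  for (a in seq_len(max(lab))) {
    px <- which(lab == a)
    best <- px[which.max(img$raw[px])]
    i <- (best - 1L) %% nrow(img$mat) + 1L
    j <- (best - 1L) %/% nrow(img$mat) + 1L
    gi <- img$rows[i]; gj <- img$cols[j]
    out[[a]] <- data.frame(
      chromA = img$chromA, posA = img$bins$start[gi],
      chromB = img$chromB, posB = img$bins$start[gj],
      binA = gi, binB = gj,
      corner_response = img$mat[best], raw_count = img$raw[best],
      area_id = a)
  }
  do.call(rbind, out)
}

#' Run the full translocation-calling chain on one chromosome pair
#'
#' @param m a `ContactMatrix` with raw counts.
#' @param chromA,chromB chromosome pair.
#' @param min_bin_reads,phi,subset,seed,kernel_size,floor_value,gain,binarise,brush
#'   stage parameters; see the individual stage functions.
#' @return data frame of candidates as in [find_candidates()].
#' @export
call_translocations_pair <- function(m, chromA, chromB, min_bin_reads = 2000,
                                     phi = 20, subset = 1e5, seed = 1,
                                     kernel_size = 7, floor_value = 1,
                                     gain = 10, binarise = 100, brush = 21) {
  img <- trans_image(m, chromA, chromB, min_bin_reads = min_bin_reads)
  img <- cnv_normalise_trans(img, phi = phi, subset = subset, seed = seed)
  img <- compartment_normalise(img)
  img <- corner_response(img, kernel_size = kernel_size,
                         floor_value = floor_value, gain = gain)
  find_candidates(img, binarise = binarise, brush = brush)
}

#' Detect translocation candidates over all chromosome pairs
#'
#' @param m a `ContactMatrix` with raw counts.
#' @param ... passed to [call_translocations_pair()].
#' @return data frame of candidates over all pairs.
#' @export
detect_translocations <- function(m, ...) {
  chroms <- unique(m$bins$chrom)
  out <- list()
  if (length(chroms) > 1)
    for (a in 1:(length(chroms) - 1)) for (b in (a + 1):length(chroms))
      out[[length(out) + 1L]] <-
        call_translocations_pair(m, chroms[a], chroms[b], ...)
  if (!length(out)) return(find_candidates(structure(list(mat = matrix(numeric(0), 0, 0)),
                                                     class = "TransImage")))
  do.call(rbind, out)
}

#' Export a review image for a breakpoint candidate
#'
#' Plots the raw trans matrix in a window around the candidate as a PNG,
#' with the manual-classification criteria printed in the header: (1) the
#' breakpoint intensity should visually stand out above background; (2) if
#' multiple potential breakpoints share the view, the considered breakpoint
#' is the most intense one; (3) in noisy regions (telomeres, centromeres,
#' low mappability) evidence of the break must propagate outside the
#' problematic region.
#'
#' @param m the `ContactMatrix` the candidate was called on.
#' @param candidate one row of a [find_candidates()] result.
#' @param path output PNG path.
#' @param window half-window around the candidate (bp).
#' @return `path`, invisibly.
#' @export
export_review_image <- function(m, candidate, path, window = 30e6) {
  full <- as_dense(m, candidate$chromA, candidate$chromB, what = "count")
  res <- m$resolution
  ia <- chrom_bins(m, candidate$chromA)
  ib <- chrom_bins(m, candidate$chromB)
  ri <- candidate$binA - ia[1] + 1L
  ci <- candidate$binB - ib[1] + 1L
  w <- ceiling(window / res)
  rr <- max(1, ri - w):min(nrow(full), ri + w)
  cc <- max(1, ci - w):min(ncol(full), ci + w)
  sub <- log1p(full[rr, cc, drop = FALSE])
  grDevices::png(path, width = 800, height = 860)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(4, 4, 7, 1))
  graphics::image(z = t(sub[rev(seq_len(nrow(sub))), , drop = FALSE]),
                  col = grDevices::hcl.colors(64, "Reds", rev = TRUE),
                  axes = FALSE,
                  main = sprintf("%s:%0.1f Mb x %s:%0.1f Mb (log1p raw counts)",
                                 candidate$chromA, candidate$posA / 1e6,
                                 candidate$chromB, candidate$posB / 1e6))
  graphics::mtext(paste("Review criteria: (1) intensity stands out above background;",
                        "(2) most intense breakpoint in view is the one considered;",
                        "(3) in noisy regions evidence must propagate outside them.",
                        sep = "\n"), side = 3, line = 0.5, cex = 0.8)
  invisible(path)
}
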