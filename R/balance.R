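#' Matrix balancing by iterative correction
#'
#' Computes per-bin weights such that every retained row of the balanced
#' genome-wide (cis + trans) matrix has the same marginal sum. Bins with
#' fewer than `min_nnz` non-zero pixels are masked (weight `NA`) before
#' iteration, as are all-zero bins. Weights are scaled so that retained
#' balanced marginals equal 1.
#'
#' @param m a `ContactMatrix` with raw counts.
#' @param max_iter maximum number of iterations.
#' @param tol convergence tolerance on the relative spread of balanced
#'   marginals (max |marginal/mean - 1|).
#' @param min_nnz minimum number of non-zero pixels for a bin to be retained.
#' @return the matrix with a `weights` vector; attribute `converged` (logical)
#'   and `spread` (final marginal spread) are attached to the weights. A
#'   non-converged fit warns rather than failing silently.
#' @export
balance <- function(m, max_iter = 200, tol = 1e-5, min_nnz = 10) {
  n <- nrow(m$bins)
  nnz <- numeric(n)
  t1 <- rowsum(rep(1, nrow(m$pixels)), m$pixels$bin1)
  t2 <- rowsum(rep(1, nrow(m$pixels)), m$pixels$bin2)
  nnz[as.integer(rownames(t1))] <- nnz[as.integer(rownames(t1))] + t1[, 1]
  nnz[as.integer(rownames(t2))] <- nnz[as.integer(rownames(t2))] + t2[, 1]
  diag_px <- m$pixels$bin1 == m$pixels$bin2
  nnz[m$pixels$bin1[diag_px]] <- nnz[m$pixels$bin1[diag_px]] - 1
  mask <- nnz < min_nnz
  w <- ifelse(mask, NA_real_, 1)

  i <- m$pixels$bin1
  j <- m$pixels$bin2
  cnt <- m$pixels$count
  spread <- Inf
  for (it in seq_len(max_iter)) {
    v <- cnt * w[i] * w[j]
    marg <- numeric(n)
    s1 <- rowsum(v, i, na.rm = TRUE)
    s2 <- rowsum(v, j, na.rm = TRUE)
    marg[as.integer(rownames(s1))] <- marg[as.integer(rownames(s1))] + s1[, 1]
    marg[as.integer(rownames(s2))] <- marg[as.integer(rownames(s2))] + s2[, 1]
    marg[i[diag_px]] <- marg[i[diag_px]] -
      ifelse(is.na(v[diag_px]), 0, v[diag_px])
    marg[mask] <- NA
    mu <- mean(marg[!mask])
    if (!is.finite(mu) || mu == 0) stopf("balancing degenerate: zero marginals")
    spread <- max(abs(marg[!mask] / mu - 1))
    if (spread < tol) break
    adj <- sqrt(marg / mu)
    adj[mask | marg == 0] <- 1
    w <- w / adj
  }
  converged <- spread < tol
  if (!converged)
    warnf("balancing did not converge in %d iterations (spread %.3g)", max_iter, spread)
  # scale so retained balanced marginals are ~1
  v <- cnt * w[i] * w[j]
  marg <- numeric(n)
  s1 <- rowsum(v, i, na.rm = TRUE); s2 <- rowsum(v, j, na.rm = TRUE)
  marg[as.integer(rownames(s1))] <- marg[as.integer(rownames(s1))] + s1[, 1]
  marg[as.integer(rownames(s2))] <- marg[as.integer(rownames(s2))] + s2[, 1]
  marg[i[diag_px]] <- marg[i[diag_px]] - ifelse(is.na(v[diag_px]), 0, v[diag_px])
  w <- w / sqrt(mean(marg[!mask]))
  attr(w, "converged") <- converged
  attr(w, "spread") <- spread
  m$weights <- w
  m
}
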