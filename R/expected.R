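#' Label bins with chromosome arms
#'
#' Assigns each bin to the p or q arm by its midpoint relative to the
#' centromere interval. Bins whose midpoint falls inside the centromere get
#' `NA` (excluded from arm-wise computation). Chromosomes absent from the
#' centromere table are treated as a single arm, with a warning.
#'
#' @param bins bin table (`chrom`, `start`, `end`).
#' @param centromeres data frame with `chrom`, `start`, `end` (0-based
#'   half-open centromere intervals), or `NULL` for single-arm chromosomes.
#' @return character vector of arm labels (`"<chrom>_p"`, `"<chrom>_q"`, or
#'   `"<chrom>"`), `NA` inside centromeres.
#' @export
split_arms <- function(bins, centromeres = NULL) {
  arm <- character(nrow(bins))
  mid <- (bins$start + bins$end) / 2
  for (chr in unique(bins$chrom)) {
    sel <- bins$chrom == chr
    ce <- if (!is.null(centromeres)) centromeres[centromeres$chrom == chr, ] else NULL
    if (is.null(ce) || nrow(ce) == 0) {
      if (!is.null(centromeres))
        warnf("no centromere entry for %s; treating as a single arm", chr)
      arm[sel] <- chr
    } else {
      arm[sel] <- ifelse(mid[sel] < ce$start[1], paste0(chr, "_p"),
                         ifelse(mid[sel] >= ce$end[1], paste0(chr, "_q"),
                                NA_character_))
    }
  }
  arm
}

#' Expected contact profile
#'
#' For cis, the mean balanced signal per bin separation within each group
#' (chromosome, or chromosome arm when `arms` is given), averaging over all
#' valid (unmasked) bin pairs at that separation including zero pixels. For
#' trans, the mean balanced signal per chromosome pair.
#'
#' @param m a balanced `ContactMatrix`.
#' @param arms optional arm labels from [split_arms()]; when supplied, cis
#'   expectations are computed per arm.
#' @return list of class `ExpectedProfile` with components `cis` (named list
#'   of per-separation mean vectors, `NA` at empty separations) and `trans`
#'   (data frame `chrom1`, `chrom2`, `mean`).
#' @export
expected_profile <- function(m, arms = NULL) {
  val <- balanced_values(m)
  grp <- if (is.null(arms)) m$bins$chrom else arms
  ok <- !is.na(m$weights)
  g1 <- grp[m$pixels$bin1]
  g2 <- grp[m$pixels$bin2]
  cis_sel <- !is.na(g1) & !is.na(g2) & g1 == g2 & !is.na(val)
  d <- m$pixels$bin2 - m$pixels$bin1

  cis <- list()
  for (g in unique(grp[!is.na(grp)])) {
    bins_g <- which(!is.na(grp) & grp == g)
    u <- ok[bins_g]
    ng <- length(bins_g)
    # valid pair count per separation (0 .. ng-1), including zero pixels
    npairs <- vapply(0:(ng - 1), function(dd) {
      if (dd == 0) sum(u) else sum(u[1:(ng - dd)] & u[(1 + dd):ng])
    }, numeric(1))
    sel <- cis_sel & g1 == g
    sums <- numeric(ng)
    if (any(sel)) {
      s <- rowsum(val[sel], d[sel])
      sums[as.integer(rownames(s)) + 1L] <- s[, 1]
    }
    mu <- ifelse(npairs > 0, sums / npairs, NA_real_)
    mu[!is.na(mu) & mu == 0] <- NA  # empty separation class
    cis[[g]] <- mu
  }

  ch1 <- m$bins$chrom[m$pixels$bin1]
  ch2 <- m$bins$chrom[m$pixels$bin2]
  trans_sel <- ch1 != ch2 & !is.na(val)
  chroms <- unique(m$bins$chrom)
  tr <- list()
  if (length(chroms) > 1) {
    for (a in seq_along(chroms)) for (b in seq_along(chroms)) {
      if (a >= b) next
      ca <- chroms[a]; cb <- chroms[b]
      sel <- trans_sel & ((ch1 == ca & ch2 == cb) | (ch1 == cb & ch2 == ca))
      nv <- sum(ok[m$bins$chrom == ca]) * sum(ok[m$bins$chrom == cb])
      tr[[length(tr) + 1L]] <- data.frame(
        chrom1 = ca, chrom2 = cb,
        mean = if (nv > 0) sum(val[sel]) / nv else NA_real_)
    }
  }
  structure(list(cis = cis,
                 trans = if (length(tr)) do.call(rbind, tr)
                         else data.frame(chrom1 = character(), chrom2 = character(),
                                         mean = numeric()),
                 arms = arms, bins = m$bins),
            class = "ExpectedProfile")
}

#' Observed-over-expected transform
#'
#' Divides each balanced pixel by the expected value at its bin separation
#' (cis; per chromosome or per arm) or by the chromosome-pair mean (trans).
#' Pixels at separations with no expected value, or involving masked or
#' centromeric bins, are dropped.
#'
#' @param m a balanced `ContactMatrix`.
#' @param scope `"cis"` (per chromosome), `"cis-per-arm"` (requires `arms`),
#'   or `"trans"`.
#' @param arms arm labels from [split_arms()] for `"cis-per-arm"`.
#' @return list with `pixels` (data frame `bin1`, `bin2`, `oe`) and
#'   `expected` (the `ExpectedProfile` used).
#' @export
observed_over_expected <- function(m, scope = c("cis", "cis-per-arm", "trans"),
                                   arms = NULL) {
  scope <- match.arg(scope)
  if (scope == "cis-per-arm" && is.null(arms))
    stopf("scope 'cis-per-arm' requires arm labels")
  prof <- expected_profile(m, arms = if (scope == "cis-per-arm") arms else NULL)
  val <- balanced_values(m)
  if (scope %in% c("cis", "cis-per-arm")) {
    grp <- if (scope == "cis-per-arm") arms else m$bins$chrom
    g1 <- grp[m$pixels$bin1]; g2 <- grp[m$pixels$bin2]
    sel <- which(!is.na(g1) & !is.na(g2) & g1 == g2 & !is.na(val))
    d <- m$pixels$bin2[sel] - m$pixels$bin1[sel]
    exp_val <- vapply(seq_along(sel), function(k) {
      prof$cis[[g1[sel[k]]]][d[k] + 1L]
    }, numeric(1))
    keep <- !is.na(exp_val) & exp_val > 0
    px <- data.frame(bin1 = m$pixels$bin1[sel][keep],
                     bin2 = m$pixels$bin2[sel][keep],
                     oe = val[sel][keep] / exp_val[keep])
  } else {
    ch1 <- m$bins$chrom[m$pixels$bin1]; ch2 <- m$bins$chrom[m$pixels$bin2]
    sel <- which(ch1 != ch2 & !is.na(val))
    key <- paste(pmin(ch1[sel], ch2[sel]), pmax(ch1[sel], ch2[sel]))
    tkey <- paste(pmin(prof$trans$chrom1, prof$trans$chrom2),
                  pmax(prof$trans$chrom1, prof$trans$chrom2))
    exp_val <- prof$trans$mean[match(key, tkey)]
    keep <- !is.na(exp_val) & exp_val > 0
    px <- data.frame(bin1 = m$pixels$bin1[sel][keep],
                     bin2 = m$pixels$bin2[sel][keep],
                     oe = val[sel][keep] / exp_val[keep])
  }
  list(pixels = px, expected = prof)
}

# Dense cis O/E matrix for one group of bins (a chromosome or an arm),
# including implicit zero pixels (O/E 0 where expected > 0). Masked bins NA.
oe_dense <- function(m, bins_idx, expected_mu) {
  nb <- length(bins_idx)
  val <- balanced_values(m)
  sel <- m$pixels$bin1 >= bins_idx[1] & m$pixels$bin2 <= bins_idx[nb] &
    m$pixels$bin1 %in% bins_idx & m$pixels$bin2 %in% bins_idx
  out <- matrix(0, nb, nb)
  if (any(sel)) {
    r <- m$pixels$bin1[sel] - bins_idx[1] + 1L
    c <- m$pixels$bin2[sel] - bins_idx[1] + 1L
    v <- val[sel]
    out[cbind(r, c)] <- v
    out[cbind(c, r)] <- v
  }
  dmat <- abs(outer(seq_len(nb), seq_len(nb), "-"))
  emat <- matrix(expected_mu[dmat + 1L], nb, nb)
  out <- out / emat
  masked <- is.na(m$weights[bins_idx])
  out[masked, ] <- NA
  out[, masked] <- NA
  out
}
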