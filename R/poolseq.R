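#' Pool-sequencing analysis configuration
#'
#' Filtering and window parameters for pooled allele-count analysis. The
#' defaults are the mitogenome-wide configuration (300 bp windows, 10 bp
#' step, minimum coverage 4, minimum count 2, pool size 80, minimum
#' covered fraction 0.6); the cox1-fragment variant uses a 392 bp window
#' with a 2 bp step.
#'
#' @param pool_size Number of pooled individuals `n`.
#' @param min_count Minimum per-allele read count `b` for a site to count
#'   as polymorphic (default 2).
#' @param min_coverage Minimum decoded depth for a site to be covered
#'   (default 4). A warning is issued when `min_coverage < 2*min_count`.
#' @param max_coverage Optional maximum depth (sites above are treated as
#'   uncovered).
#' @param window Window size in bp (default 300).
#' @param step Step size in bp (default 10).
#' @param min_covered_fraction Minimum fraction of covered sites for a
#'   window's statistics to be defined (default 0.6).
#' @return List of class `poolConfig`.
#' @export
poolConfig <- function(pool_size = 80L, min_count = 2L, min_coverage = 4L,
                       max_coverage = NULL, window = 300L, step = 10L,
                       min_covered_fraction = 0.6) {
  stopifnot(min_count >= 1L, pool_size >= 1L, window >= 1L, step >= 1L,
            min_covered_fraction > 0, min_covered_fraction <= 1)
  if (min_coverage < 2L * min_count)
    warning("min_coverage < 2*min_count: no site can carry two alleles ",
            "at the minimum count")
  structure(list(pool_size = as.integer(pool_size),
                 min_count = as.integer(min_count),
                 min_coverage = as.integer(min_coverage),
                 max_coverage = if (is.null(max_coverage)) NULL
                                else as.integer(max_coverage),
                 window = as.integer(window), step = as.integer(step),
                 min_covered_fraction = min_covered_fraction),
            class = "poolConfig")
}

siteTotals <- function(sites) sites$A + sites$C + sites$G + sites$T

#' Call SNPs from pooled allele counts
#'
#' A site is a SNP iff its decoded depth is within the coverage bounds and
#' at least two alleles each reach the minimum count. Sites failing the
#' filters are marked covered/uncovered, never dropped.
#'
#' @param sites Data frame as returned by [readPileup()] or
#'   [simulatePool()] (`pos`, `ref`, `A`, `C`, `G`, `T`), sorted by
#'   position.
#' @param config A [poolConfig()].
#' @return `sites` with added columns `total` (decoded depth), `covered`,
#'   `is_snp`, `major`, `minor`, `maf` (minor count / total counted).
#' @export
callSnps <- function(sites, config) {
  if (is.unsorted(sites$pos, strictly = TRUE))
    stop("sites must be sorted by strictly increasing position")
  cnt <- as.matrix(sites[, DNA_BASES])
  total <- rowSums(cnt)
  covered <- total >= config$min_coverage
  if (!is.null(config$max_coverage))
    covered <- covered & total <= config$max_coverage
  nAllelesPassing <- rowSums(cnt >= config$min_count)
  isSnp <- covered & nAllelesPassing >= 2L
  ord <- t(apply(cnt, 1L, order, decreasing = TRUE))
  major <- DNA_BASES[ord[, 1L]]
  minor <- DNA_BASES[ord[, 2L]]
  minorCnt <- cnt[cbind(seq_len(nrow(cnt)), ord[, 2L])]
  sites$total <- total
  sites$covered <- covered
  sites$is_snp <- isSnp
  sites$major <- major
  sites$minor <- ifelse(isSnp, minor, NA_character_)
  sites$maf <- ifelse(isSnp, minorCnt / total, NA_real_)
  sites
}

#' Unbiased per-site heterozygosity of pooled reads
#'
#' `(M/(M-1)) * (1 - sum((c_a/M)^2))` over the counted bases, the
#' read-level analogue of gene diversity and the building block of the
#' pool estimate of pi.
#'
#' @param counts Numeric vector of base counts (A,C,G,T).
#' @return Heterozygosity; `NA` when fewer than 2 reads are counted.
#' @export
siteHeterozygosity <- function(counts) {
  M <- sum(counts)
  if (M < 2) return(NA_real_)
  M / (M - 1) * (1 - sum((counts / M)^2))
}

.poolCorrCache <- new.env(parent = emptyenv())

#' Pool correction factors for diversity estimators
#'
#' Exact expectation factors under the two-stage pooled-sampling model:
#' a site carries `k` derived copies among the `n` pooled chromosomes
#' (`k = 1..n-1`, weighted proportionally to `1/k` as under the neutral
#' site-frequency spectrum), the derived read count is
#' `m ~ Binomial(M, k/n)`, and the site is detected iff
#' `b <= m <= M - b`. The pi factor additionally carries the
#' pairwise-diversity weight `2m(M-m)/(M(M-1))` of the read sample.
#' Dividing the summed observed statistic by the factor (and the window
#' size) yields an unbiased estimate of the per-site mutation parameter:
#' `theta_pi = sum(site heterozygosity) / (w * pi_denominator)` and
#' `theta_W = S / (w * watterson_denominator)`. Without truncation or
#' pool distortion `pi_denominator -> 1` and
#' `watterson_denominator -> a1(n)` (the classical Watterson
#' denominator); `watterson_denominator/a1` approaches 1 only when the
#' depth is large relative to the pool size.
#'
#' Computed by exact enumeration over `k` (binomial tail sums over `m`)
#' and memoized per distinct `(M, n, b)`.
#'
#' @param M Decoded site depth (reads counted).
#' @param n Pool size (chromosomes), >= 2.
#' @param b Minimum allele count, `1 <= b <= M/2`.
#' @return List `pi_denominator`, `watterson_denominator`, `a1`.
#' @export
poolCorrections <- function(M, n, b) {
  if (b > M / 2) stop("min_count b > M/2: no site can pass the filter")
  if (n < 2L) stop("pool size must be >= 2")
  key <- paste(M, n, b, sep = "_")
  hit <- .poolCorrCache[[key]]
  if (!is.null(hit)) return(hit)
  k <- seq_len(n - 1L)
  p <- k / n
  # detection probability P(b <= m <= M-b)
  det <- pbinom(M - b, M, p) - pbinom(b - 1L, M, p)
  wat <- sum(det / k)
  # pi weight: E[2m(M-m)/(M(M-1)) ; b <= m <= M-b]
  # full-range expectation is 2p(1-p); subtract the (short) tails
  tails <- numeric(n - 1L)
  mLow <- if (b >= 1L) 0:(b - 1L) else integer(0)
  mHigh <- (M - b + 1L):M
  for (i in seq_along(k)) {
    tl <- sum(dbinom(mLow, M, p[[i]]) * 2 * mLow * (M - mLow)) +
          sum(dbinom(mHigh, M, p[[i]]) * 2 * mHigh * (M - mHigh))
    tails[[i]] <- tl / (M * (M - 1))
  }
  piD <- sum((2 * p * (1 - p) - tails) / k)
  res <- list(pi_denominator = piD, watterson_denominator = wat,
              a1 = sum(1 / k))
  .poolCorrCache[[key]] <- res
  res
}

#' Windowed pool-corrected diversity statistics
#'
#' Sliding windows over the reference span: per window the covered
#' fraction is the number of sites passing the coverage filters divided
#' by the window size (masked positions count as uncovered); `theta_pi`
#' sums the per-site read heterozygosity of called SNPs divided by the
#' site's pi correction factor, over the window size; `theta_w` does the
#' analogous sum of `1/watterson_denominator` over SNP sites. Tajima's D
#' is the pool-adapted variant: Tajima's variance evaluated at effective
#' sample size `min(pool_size, floor(mean coverage))` with `S` the SNP
#' count. Windows below the minimum covered fraction (or with no SNP)
#' have their statistics flagged undefined (`NA`).
#'
#' @param sites Site-count data frame (`pos`, `A`, `C`, `G`, `T`), sorted.
#' @param config A [poolConfig()].
#' @param ref_length Length of the reference span (defaults to the last
#'   position present).
#' @param mask Optional two-column data frame (`start`, `end`, 1-based
#'   inclusive) of positions to exclude (e.g. the repeat region).
#' @return Data frame of window statistics: `start`, `end`, `n_snps`,
#'   `covered_fraction`, `theta_pi`, `theta_w`, `tajimas_d`.
#' @export
windowedStats <- function(sites, config, ref_length = NULL, mask = NULL) {
  if (is.null(ref_length)) ref_length <- max(sites$pos)
  w <- config$window
  if (w > ref_length) stop("window exceeds reference span")
  called <- callSnps(sites, config)
  masked <- rep(FALSE, ref_length)
  if (!is.null(mask))
    for (r in seq_len(nrow(mask)))
      masked[seq(mask$start[[r]], mask$end[[r]])] <- TRUE
  keep <- !masked[called$pos]
  called$covered <- called$covered & keep
  called$is_snp <- called$is_snp & keep
  cnt <- as.matrix(called[, DNA_BASES])
  n <- config$pool_size
  b <- config$min_count
  siteH <- siteTheta <- siteW <- rep(0, ref_length)
  snpIdx <- which(called$is_snp)
  for (i in snpIdx) {
    M <- called$total[[i]]
    corr <- poolCorrections(M, n, b)
    h <- siteHeterozygosity(cnt[i, ])
    siteTheta[[called$pos[[i]]]] <- h / corr$pi_denominator
    siteW[[called$pos[[i]]]] <- 1 / corr$watterson_denominator
  }
  coveredPos <- rep(FALSE, ref_length)
  coveredPos[called$pos[called$covered]] <- TRUE
  snpPos <- rep(FALSE, ref_length)
  snpPos[called$pos[called$is_snp]] <- TRUE
  totals <- rep(NA_real_, ref_length)
  totals[called$pos] <- called$total
  starts <- seq(1L, ref_length - w + 1L, by = config$step)
  out <- lapply(starts, function(s) {
    span <- s:(s + w - 1L)
    covFrac <- sum(coveredPos[span]) / w
    nSnps <- sum(snpPos[span])
    if (covFrac < config$min_covered_fraction) {
      tp <- tw <- td <- NA_real_
    } else {
      tp <- sum(siteTheta[span]) / w
      tw <- sum(siteW[span]) / w
      td <- NA_real_
      if (nSnps >= 1L) {
        nEff <- min(n, floor(mean(totals[span][coveredPos[span]])))
        if (nEff >= 4L) {
          k <- tajimaConstants(nEff)
          varD <- k$e1 * nSnps + k$e2 * nSnps * (nSnps - 1)
          if (varD > 0) td <- (tp - tw) * w / sqrt(varD)
        }
      }
    }
    data.frame(start = s, end = s + w - 1L, n_snps = nSnps,
               covered_fraction = covFrac, theta_pi = tp, theta_w = tw,
               tajimas_d = td)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Minimum detectable allele frequency of a pooled analysis
#'
#' The smallest reportable allele frequency at a site of depth `M` is
#' `b/M`; the per-individual coverage of the pool is `M/pool_size`.
#'
#' @param config A [poolConfig()].
#' @param depth Site depth `M`.
#' @return List `min_frequency`, `per_individual_coverage`.
#' @export
minDetectableFrequency <- function(config, depth) {
  list(min_frequency = config$min_count / depth,
       per_individual_coverage = depth / config$pool_size)
}
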