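#' Per-site allele frequencies from an individual-based alignment
#'
#' For each polymorphic site of a gap-free aligned fragment, reports the
#' major and minor allele and the minor-allele frequency (counts over the
#' sequences carrying an unambiguous base at that site). The minimum
#' possible non-zero frequency is `1/n`.
#'
#' @param aln A [HapAlignment-class].
#' @return Data frame with `pos`, `major`, `minor`, `freq`
#'   (minor-allele frequency), `n_used`.
#' @export
individualAlleleFrequencies <- function(aln) {
  m <- alnMatrix(aln)
  out <- list()
  for (s in seq_len(ncol(m))) {
    col <- m[, s]
    col <- col[col %in% DNA_BASES]
    tab <- sort(table(col), decreasing = TRUE)
    if (length(tab) < 2L) next
    out[[length(out) + 1L]] <- data.frame(
      pos = s, major = names(tab)[[1L]], minor = names(tab)[[2L]],
      freq = as.numeric(tab[[2L]]) / sum(tab), n_used = sum(tab))
  }
  if (length(out) == 0L)
    return(data.frame(pos = integer(), major = character(),
                      minor = character(), freq = numeric(),
                      n_used = integer()))
  do.call(rbind, out)
}

#' Singleton allele-frequency threshold
#'
#' The lowest allele frequency a single carrier can produce in a sample
#' of the given size: `1/sample_size`. For a pool of 80 individuals this
#' is 0.0125; for 68 sequenced individuals, 0.0147.
#'
#' @param sample_size Number of individuals (>= 1).
#' @return `1/sample_size`.
#' @examples
#' singletonThreshold(80)
#' @export
singletonThreshold <- function(sample_size) {
  if (length(sample_size) != 1L || is.na(sample_size) || sample_size < 1)
    stop("sample_size must be >= 1")
  1 / sample_size
}

roundHalfUp <- function(x) floor(x + 0.5)

#' Compare individual-based and pooled SNP sets
#'
#' Matches the two call sets by position on the shared fragment, reports
#' the shared and source-unique sites, the shared percentages of each
#' source (rounded to the nearest integer, raw ratios also kept), and
#' flags each pool-unique site whose minor-allele frequency falls below
#' the individual-based detection floor (`1/individual_n`) and/or below
#' the pooled singleton threshold (`1/pool_size`). Flags are advisory
#' annotations; no record is removed.
#'
#' @param individual_records Data frame with `pos`, `freq` (and
#'   optionally `minor`) from [individualAlleleFrequencies()].
#' @param pool_records Data frame with `pos`, `freq` = `maf` (and
#'   optionally `minor`) from [callSnps()] SNP rows.
#' @param pool_size Number of pooled individuals.
#' @param individual_n Number of individually sequenced haplotypes.
#' @return List of class `snpComparison`: `shared` (paired frequency
#'   table), `unique_individual`, `unique_pool` (with logical columns
#'   `below_individual_floor`, `below_pool_singleton`), `pct_of_pool`,
#'   `pct_of_individual`, `ratio_pool`, `ratio_individual`.
#' @export
compareSnpSets <- function(individual_records, pool_records, pool_size,
                           individual_n) {
  if (anyDuplicated(individual_records$pos))
    stop("duplicate positions in individual records")
  if (anyDuplicated(pool_records$pos))
    stop("duplicate positions in pool records")
  sharedPos <- intersect(individual_records$pos, pool_records$pos)
  si <- individual_records[match(sharedPos, individual_records$pos), ,
                           drop = FALSE]
  sp <- pool_records[match(sharedPos, pool_records$pos), , drop = FALSE]
  shared <- data.frame(pos = sharedPos,
                       freq_individual = si$freq, freq_pool = sp$freq)
  if (!is.null(si$minor) && !is.null(sp$minor)) {
    shared$minor_individual <- si$minor
    shared$minor_pool <- sp$minor
    dis <- which(si$minor != sp$minor)
    if (length(dis))
      warning("shared positions disagree on minor allele: ",
              paste(sharedPos[dis], collapse = ", "))
  }
  ui <- individual_records[!individual_records$pos %in% sharedPos, ,
                           drop = FALSE]
  up <- pool_records[!pool_records$pos %in% sharedPos, , drop = FALSE]
  up$below_individual_floor <- up$freq < singletonThreshold(individual_n)
  up$below_pool_singleton <- up$freq < singletonThreshold(pool_size)
  nPool <- nrow(pool_records); nInd <- nrow(individual_records)
  structure(list(
    shared = shared, unique_individual = ui, unique_pool = up,
    pct_of_pool = if (nPool) roundHalfUp(100 * nrow(shared) / nPool) else NA,
    pct_of_individual = if (nInd) roundHalfUp(100 * nrow(shared) / nInd)
                        else NA,
    ratio_pool = if (nPool) nrow(shared) / nPool else NA_real_,
    ratio_individual = if (nInd) nrow(shared) / nInd else NA_real_),
    class = "snpComparison")
}

#' @export
print.snpComparison <- function(x, ...) {
  cat(sprintf(paste0("SNP concordance: %d shared (%d%% of pool, %d%% of",
                     " individual), %d pool-unique, %d individual-unique\n"),
              nrow(x$shared), x$pct_of_pool, x$pct_of_individual,
              nrow(x$unique_pool), nrow(x$unique_individual)))
  if (nrow(x$unique_pool))
    cat("  pool-unique below individual floor:",
        sum(x$unique_pool$below_individual_floor),
        "; below pool singleton:",
        sum(x$unique_pool$below_pool_singleton), "\n")
  invisible(x)
}

#' Frequency agreement across shared polymorphic sites
#'
#' Per-pair signed and absolute frequency differences between the
#' individual-based and pooled estimates at shared sites, with mean and
#' maximum absolute difference and the rank correlation across pairs.
#'
#' @param shared_pairs Data frame with `freq_individual`, `freq_pool`
#'   (the `shared` element of [compareSnpSets()]).
#' @return List `table` (per-pair differences), `mean_abs_diff`,
#'   `max_abs_diff`, `rank_correlation`.
#' @export
frequencyAgreement <- function(shared_pairs) {
  if (is.null(shared_pairs) || nrow(shared_pairs) == 0L)
    stop("no shared pairs to compare")
  d <- shared_pairs$freq_pool - shared_pairs$freq_individual
  rc <- if (nrow(shared_pairs) > 1L)
    suppressWarnings(cor(shared_pairs$freq_individual,
                         shared_pairs$freq_pool, method = "spearman"))
  else NA_real_
  list(table = data.frame(pos = shared_pairs$pos,
                          freq_individual = shared_pairs$freq_individual,
                          freq_pool = shared_pairs$freq_pool,
                          diff = d, abs_diff = abs(d)),
       mean_abs_diff = mean(abs(d)), max_abs_diff = max(abs(d)),
       rank_correlation = rc)
}
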