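#' Length of a 1-based inclusive span on a (possibly circular) genome
#'
#' @param start,end 1-based inclusive coordinates; `end < start` denotes
#'   a span wrapping the circular origin.
#' @param genome_length Genome length in bp.
#' @return Span length: `end - start + 1`, or
#'   `genome_length - start + 1 + end` for a wrapped span.
#' @examples
#' spanLength(536, 1181, 15575)    # 646
#' spanLength(14965, 426, 15575)   # 1037
#' @export
spanLength <- function(start, end, genome_length) {
  ifelse(end >= start, end - start + 1L, genome_length - start + 1L + end)
}

#' Extract a region from a circular genome
#'
#' Inclusive 1-based subsequence; if `end < start` and the genome is
#' circular, the tail and head are concatenated across the origin.
#'
#' @param genome A [CircularGenome-class].
#' @param start,end 1-based inclusive coordinates.
#' @return The subsequence string.
#' @export
extractRegion <- function(genome, start, end) {
  L <- genomeLength(genome)
  if (start < 1L || start > L || end < 1L || end > L)
    stop("coordinates must be within 1..", L)
  s <- genomeSequence(genome)
  if (end >= start) return(substr(s, start, end))
  if (!isCircular(genome))
    stop("wrapped span requested on a non-circular genome")
  paste0(substr(s, start, L), substr(s, 1L, end))
}

revComp <- function(s) {
  chartr("ACGTN", "TGCAN",
         paste(rev(strsplit(s, "")[[1L]]), collapse = ""))
}

#' Translate under the echinoderm/flatworm mitochondrial code
#'
#' NCBI translation table 9: `AGA`/`AGG` encode Ser, `AAA` encodes Asn
#' and `TGA` encodes Trp. Sequences whose length is not a multiple of
#' three are accepted when the remainder is an abbreviated stop tail
#' (`"T"` or `"TA"`, completed to `TAA` by transcript polyadenylation),
#' which is emitted as the stop marker `*`. Codons containing non-ACGT
#' characters translate to `X` with a warning.
#'
#' @param sequence Nucleotide string.
#' @param code NCBI genetic-code id (default `"9"`).
#' @return Amino-acid string (stops as `*`).
#' @examples
#' translateMito("TGAAAAAGA")  # "WNS"
#' @export
translateMito <- function(sequence, code = "9") {
  sequence <- toupper(sequence)
  L <- nchar(sequence)
  if (L == 0L) return("")
  rem <- L %% 3L
  tailSeq <- NULL
  if (rem != 0L) {
    tailSeq <- substr(sequence, L - rem + 1L, L)
    if (!(tailSeq %in% c("T", "TA")))
      stop("length not a multiple of 3 and tail '", tailSeq,
           "' is not an abbreviated stop")
    sequence <- substr(sequence, 1L, L - rem)
  }
  tbl <- Biostrings::getGeneticCode(code)
  codons <- substring(sequence, seq(1L, nchar(sequence), 3L),
                      seq(3L, nchar(sequence), 3L))
  aa <- tbl[codons]
  bad <- is.na(aa)
  if (any(bad)) {
    warning("non-ACGT codon(s) translated to X: ",
            paste(unique(codons[bad]), collapse = ", "))
    aa[bad] <- "X"
  }
  paste0(paste(aa, collapse = ""), if (!is.null(tailSeq)) "*" else "")
}

#' Scan a circular genome for open reading frames
#'
#' Both strands, all three frames, circular-aware. An ORF runs from an
#' allowed start codon to the first in-frame canonical stop (`TAA`/`TAG`
#' under the flatworm code, where `TGA` is Trp). When
#' `allow_abbreviated_stops` and downstream feature boundaries are
#' supplied, an ORF may instead end at a `T` or `TA` abutting such a
#' boundary (abbreviated stops are only called against a supplied
#' boundary, mirroring annotation practice; abbreviated calling is on the
#' forward strand). All allowed in-frame starts for each stop are
#' reported, so a truth gene is recovered exactly among the candidates.
#'
#' @param genome A [CircularGenome-class].
#' @param starts Allowed start codons (default `ATG`, `GTG`, `ATT`).
#' @param min_length Minimum ORF length in bp including the stop
#'   (default 150; must be >= 3).
#' @param allow_abbreviated_stops Logical (default `TRUE` when
#'   `boundaries` supplied).
#' @param boundaries Optional integer vector of 1-based positions at
#'   which a downstream feature starts (the ORF must end at
#'   `boundary - 1`).
#' @return Data frame of candidate ORFs: `start`, `end` (1-based
#'   inclusive, wrapped when crossing the origin), `strand`, `length`,
#'   `start_codon`, `stop_codon`.
#' @export
scanOrfs <- function(genome, starts = c("ATG", "GTG", "ATT"),
                     min_length = 150L,
                     allow_abbreviated_stops = !is.null(boundaries),
                     boundaries = NULL) {
  if (min_length < 3L) stop("min_length must be >= 3")
  L <- genomeLength(genome)
  fwd <- genomeSequence(genome)
  out <- list()
  scanStrand <- function(s, strand) {
    # scan on the doubled sequence to cross the origin; map back mod L
    dbl <- if (isCircular(genome)) paste0(s, s) else s
    n <- nchar(dbl)
    codonAt <- function(p) substr(dbl, p, p + 2L)
    for (frame in 0:2) {
      positions <- seq(1L + frame, n - 2L, by = 3L)
      cods <- substring(dbl, positions, positions + 2L)
      stopIdx <- which(cods %in% c("TAA", "TAG"))
      startIdx <- which(cods %in% starts)
      for (si in startIdx) {
        p0 <- positions[[si]]
        if (p0 > L) next                     # dedupe: starts in first copy only
        nxt <- stopIdx[stopIdx > si]
        if (length(nxt)) {
          pe <- positions[[nxt[[1L]]]] + 2L
          if (pe - p0 + 1L <= L && pe - p0 + 1L >= min_length) {
            e <- ((pe - 1L) %% L) + 1L
            out[[length(out) + 1L]] <<- data.frame(
              start = p0, end = e, strand = strand,
              length = pe - p0 + 1L, start_codon = cods[[si]],
              stop_codon = codonAt(positions[[nxt[[1L]]]]))
          }
        }
        if (strand == "+" && allow_abbreviated_stops &&
            !is.null(boundaries)) {
          firstStop <- if (length(nxt)) positions[[nxt[[1L]]]] else n + 1L
          for (bpos in boundaries) {
            for (wrapOff in c(0L, L)) {
              bEnd <- bpos - 1L + wrapOff       # ORF must end here
              if (bEnd <= p0 || bEnd >= firstStop + 2L) next
              len <- bEnd - p0 + 1L
              tailLen <- len %% 3L
              if (tailLen == 0L || len > L || len < min_length) next
              tailSeq <- substr(dbl, bEnd - tailLen + 1L, bEnd)
              if (!(tailSeq %in% c("T", "TA"))) next
              out[[length(out) + 1L]] <<- data.frame(
                start = p0, end = ((bEnd - 1L) %% L) + 1L,
                strand = strand, length = len, start_codon = cods[[si]],
                stop_codon = tailSeq)
            }
          }
        }
      }
    }
  }
  scanStrand(fwd, "+")
  rc <- revComp(fwd)
  outBefore <- length(out)
  scanStrand(rc, "-")
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(start = integer(), end = integer(), strand = character(),
               length = integer(), start_codon = character(),
               stop_codon = character())
  # map reverse-strand coordinates back to forward coordinates
  if (nrow(res)) {
    rev <- res$strand == "-"
    if (any(rev)) {
      s2 <- L - res$end[rev] + 1L       # rev-comp position p -> L - p + 1
      e2 <- L - res$start[rev] + 1L
      res$start[rev] <- ((s2 - 1L) %% L) + 1L
      res$end[rev] <- ((e2 - 1L) %% L) + 1L
    }
    res <- unique(res)
    rownames(res) <- NULL
  }
  res
}

#' GC content of a genome span
#'
#' `100 * (G + C) / span length`, reported as a percentage.
#'
#' @param genome A [CircularGenome-class] (or a plain nucleotide string).
#' @param start,end Optional 1-based inclusive span (wrap allowed on
#'   circular genomes); default is the whole sequence.
#' @return Percentage GC.
#' @export
gcContent <- function(genome, start = NULL, end = NULL) {
  s <- if (is(genome, "CircularGenome")) {
    if (is.null(start)) genomeSequence(genome)
    else extractRegion(genome, start, end)
  } else {
    g <- toupper(genome)
    if (is.null(start)) g else substr(g, start, end)
  }
  ch <- strsplit(s, "")[[1L]]
  100 * sum(ch %in% c("G", "C")) / length(ch)
}

#' AT content of a genome span
#'
#' Complement of [gcContent()] for gap/N-free spans.
#'
#' @inheritParams gcContent
#' @return Percentage AT.
#' @export
atContent <- function(genome, start = NULL, end = NULL) {
  s <- if (is(genome, "CircularGenome")) {
    if (is.null(start)) genomeSequence(genome)
    else extractRegion(genome, start, end)
  } else {
    g <- toupper(genome)
    if (is.null(start)) g else substr(g, start, end)
  }
  ch <- strsplit(s, "")[[1L]]
  100 * sum(ch %in% c("A", "T")) / length(ch)
}

#' Detect tandem repeat arrays
#'
#' Greedy period scan: for each candidate period, consecutive
#' period-length blocks are extended while each matches the previous copy
#' at >= 80% identity; the final partial copy is counted fractionally.
#' Overlapping reports (e.g. the same array at a multiple of its true
#' period) are merged to the highest-copy array. On circular genomes the
#' scan crosses the origin.
#'
#' @param genome A [CircularGenome-class] or nucleotide string.
#' @param min_period,max_period Period range in bp (`min_period >= 2`).
#' @param min_copies Minimum copy number to report (default 3).
#' @param min_identity Consecutive-copy identity threshold (default 0.8).
#' @return Data frame `start`, `end`, `period`, `copies` (one decimal),
#'   `consensus`.
#' @export
findTandemRepeats <- function(genome, min_period = 2L, max_period = 120L,
                              min_copies = 3, min_identity = 0.8) {
  if (min_period < 2L) stop("min_period must be >= 2")
  circ <- is(genome, "CircularGenome") && isCircular(genome)
  s <- if (is(genome, "CircularGenome")) genomeSequence(genome)
       else toupper(genome)
  L <- nchar(s)
  dbl <- if (circ) paste0(s, substr(s, 1L, min(L, max_period * 30L))) else s
  ch <- strsplit(dbl, "")[[1L]]
  n <- length(ch)
  hits <- list()
  for (p in min_period:min(max_period, floor(n / 2))) {
    match <- ch[seq_len(n - p)] == ch[(p + 1L):n]
    cs <- cumsum(c(0L, match))
    blockId <- function(a, b) (cs[[b + 1L]] - cs[[a]]) / (b - a + 1L)
    i <- 1L
    while (i + 2L * p - 1L <= n) {
      # does copy starting at i match the next copy?
      if (blockId(i, i + p - 1L) >= min_identity) {
        copies <- 2
        j <- i + p                       # start of last confirmed copy
        while (j + 2L * p - 1L <= n && blockId(j, j + p - 1L) >= min_identity) {
          copies <- copies + 1
          j <- j + p
        }
        # fractional final copy
        rem <- min(p - 1L, n - (j + p - 1L))
        frac <- 0L
        if (rem > 0L) {
          matched <- cs[[j + rem + 1L]] - cs[[j]]
          if (matched / rem >= min_identity) frac <- rem
        }
        endPos <- j + p - 1L + frac
        nCopies <- (endPos - i + 1L) / p
        if (nCopies >= min_copies && i <= L)
          hits[[length(hits) + 1L]] <- data.frame(
            start = i, end = endPos, period = p, copies = nCopies)
        i <- endPos + 1L
      } else i <- i + 1L
    }
  }
  if (length(hits) == 0L)
    return(data.frame(start = integer(), end = integer(),
                      period = integer(), copies = numeric(),
                      consensus = character()))
  h <- do.call(rbind, hits)
  # merge overlaps: keep the highest-copy array among overlapping reports
  h <- h[order(-h$copies, h$period), , drop = FALSE]
  keep <- logical(nrow(h))
  for (r in seq_len(nrow(h))) {
    overl <- keep & !(h$end < h$start[[r]] | h$start > h$end[[r]])
    if (!any(overl)) keep[[r]] <- TRUE
  }
  h <- h[keep, , drop = FALSE]
  h$consensus <- vapply(seq_len(nrow(h)), function(r) {
    p <- h$period[[r]]
    nFull <- floor((h$end[[r]] - h$start[[r]] + 1L) / p)
    mat <- matrix(ch[h$start[[r]]:(h$start[[r]] + nFull * p - 1L)],
                  nrow = p)
    paste(apply(mat, 1L, function(x)
      names(sort(table(x), decreasing = TRUE))[[1L]]), collapse = "")
  }, character(1))
  h$copies <- round(h$copies, 1L)
  # map back onto the circle
  h$end <- ifelse(h$end > L, ((h$end - 1L) %% L) + 1L, h$end)
  h <- h[order(h$start), , drop = FALSE]
  rownames(h) <- NULL
  h
}

#' Locate non-coding regions between annotated features
#'
#' Reports maximal inter-feature gaps of at least `min_length` bp as NCR
#' features with their GC content; a gap wrapping the circular origin is
#' reported with `end < start`.
#'
#' @param features Data frame with `start`, `end` (1-based inclusive,
#'   wrap allowed), non-overlapping after wrap normalisation.
#' @param genome A [CircularGenome-class].
#' @param min_length Minimum gap length to report (default 50).
#' @return Data frame of NCR features: `name`, `kind`, `start`, `end`,
#'   `length`, `gc`.
#' @export
locateNcrs <- function(features, genome, min_length = 50L) {
  L <- genomeLength(genome)
  covered <- rep(FALSE, L)
  for (r in seq_len(nrow(features))) {
    st <- features$start[[r]]; en <- features$end[[r]]
    idx <- if (en >= st) st:en else c(st:L, 1:en)
    covered[idx] <- TRUE
  }
  if (all(covered)) return(data.frame(
    name = character(), kind = character(), start = integer(),
    end = integer(), length = integer(), gc = numeric()))
  gapRuns <- rle(covered)
  pos <- cumsum(c(1L, gapRuns$lengths))
  gaps <- which(!gapRuns$values)
  spans <- data.frame(start = pos[gaps],
                      end = pos[gaps] + gapRuns$lengths[gaps] - 1L)
  # merge a trailing gap with a leading gap across the origin
  if (isCircular(genome) && nrow(spans) > 1L &&
      spans$start[[1L]] == 1L && spans$end[[nrow(spans)]] == L) {
    spans$start[[1L]] <- spans$start[[nrow(spans)]]
    spans <- spans[-nrow(spans), , drop = FALSE]
  } else if (isCircular(genome) && nrow(spans) == 1L &&
             spans$start[[1L]] == 1L && spans$end[[1L]] == L) {
    # nothing covered at all: single full-circle gap, leave as is
  }
  lens <- spanLength(spans$start, spans$end, L)
  spans <- spans[lens >= min_length, , drop = FALSE]
  lens <- lens[lens >= min_length]
  if (nrow(spans) == 0L) return(data.frame(
    name = character(), kind = character(), start = integer(),
    end = integer(), length = integer(), gc = numeric()))
  data.frame(name = paste0("NCR", seq_len(nrow(spans))), kind = "NCR",
             start = spans$start, end = spans$end, length = lens,
             gc = vapply(seq_len(nrow(spans)), function(r)
               gcContent(genome, spans$start[[r]], spans$end[[r]]),
               numeric(1)))
}
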