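alnMatrix <- function(aln) {
  m <- do.call(rbind, strsplit(alnSequences(aln), ""))
  rownames(m) <- names(alnSequences(aln))
  m
}

#' Collapse an alignment into haplotypes
#'
#' Groups sequences by exact identity (gaps and `N` treated as ordinary
#' states for identity) and counts polymorphic sites: sites at which at
#' least two distinct non-`N` states are observed, with the gap counted
#' as a fifth state.
#'
#' @param aln A [HapAlignment-class].
#' @return A [HaplotypeTable-class].
#' @examples
#' aln <- HapAlignment(c(a = "ACGT", b = "ACGT", c = "ACGA"))
#' collapseHaplotypes(aln)
#' @export
collapseHaplotypes <- function(aln) {
  seqs <- alnSequences(aln)
  if (length(seqs) == 0L) stop("empty alignment")
  groups <- split(names(seqs), factor(seqs, levels = unique(seqs)))
  haps <- names(groups)
  m <- alnMatrix(aln)
  poly <- sum(apply(m, 2L, function(col) {
    states <- unique(col[col != "N"])
    length(states) >= 2L
  }))
  new("HaplotypeTable", haplotypes = haps,
      counts = as.integer(lengths(groups)),
      members = unname(groups), nPolymorphic = as.integer(poly))
}

#' Haplotype (gene) diversity
#'
#' Nei's unbiased estimator `h = n/(n-1) * (1 - sum(f_i^2))` with `f_i`
#' the haplotype relative frequencies.
#'
#' @param table A [HaplotypeTable-class] (or an integer vector of
#'   haplotype counts).
#' @return Numeric in `[0, 1]`.
#' @export
haplotypeDiversity <- function(table) {
  counts <- if (is(table, "HaplotypeTable")) hapCounts(table) else table
  n <- sum(counts)
  if (n < 2L) stop("haplotype diversity undefined for n < 2")
  n / (n - 1) * (1 - sum((counts / n)^2))
}

# per-pair (differences, comparable sites); sites with N or gap in either
# member are excluded for that pair
pairDiff <- function(a, b) {
  ok <- a %in% DNA_BASES & b %in% DNA_BASES
  c(diff = sum(a[ok] != b[ok]), comp = sum(ok))
}

#' Nucleotide diversity (pi)
#'
#' Mean pairwise proportion of differing sites over all unordered pairs of
#' sequences. For each pair, sites at which either member carries `N` or a
#' gap are excluded from that pair's numerator and denominator.
#'
#' @param aln A [HapAlignment-class].
#' @return Per-site nucleotide diversity in `[0, 1]`.
#' @export
nucleotideDiversity <- function(aln) {
  n <- sampleSize(aln)
  if (n < 2L) stop("nucleotide diversity undefined for n < 2")
  m <- alnMatrix(aln)
  ids <- rownames(m)
  tot <- 0
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d <- pairDiff(m[i, ], m[j, ])
    if (d[["comp"]] == 0L)
      stop("no comparable sites between '", ids[[i]], "' and '", ids[[j]], "'")
    tot <- tot + d[["diff"]] / d[["comp"]]
  }
  tot / (n * (n - 1) / 2)
}

#' Tajima's neutrality-test constants
#'
#' The standard sample-size constants of Tajima's D.
#'
#' @param n Sample size (>= 2).
#' @return Named list `a1, a2, b1, b2, c1, c2, e1, e2`.
#' @export
tajimaConstants <- function(n) {
  if (n < 2L) stop("n must be >= 2")
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = e1, e2 = e2)
}

#' Tajima's D from an alignment
#'
#' `D = (pi_total - S/a1) / sqrt(e1*S + e2*S*(S-1))` with `pi_total` the
#' mean number of pairwise differences and `S` the number of segregating
#' sites (sites with at least two distinct states among `A,C,G,T`; gap/N
#' columns are handled by pairwise exclusion in `pi_total`).
#'
#' @param aln A [HapAlignment-class] with at least 4 sequences.
#' @return List of class `tajimaD` with `D`, `S`, `pi_total` and the
#'   constants of [tajimaConstants()].
#' @export
tajimasD <- function(aln) {
  n <- sampleSize(aln)
  if (n < 4L) stop("Tajima's D requires n >= 4")
  m <- alnMatrix(aln)
  segCols <- which(apply(m, 2L, function(col) {
    st <- unique(col[col %in% DNA_BASES])
    length(st) >= 2L
  }))
  S <- length(segCols)
  if (S == 0L) stop("Tajima's D undefined: no segregating sites")
  ms <- m[, segCols, drop = FALSE]
  piTot <- 0
  npairs <- n * (n - 1) / 2
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    a <- ms[i, ]; b <- ms[j, ]
    ok <- a %in% DNA_BASES & b %in% DNA_BASES
    piTot <- piTot + sum(a[ok] != b[ok])
  }
  piTot <- piTot / npairs
  k <- tajimaConstants(n)
  varD <- k$e1 * S + k$e2 * S * (S - 1)
  D <- (piTot - S / k$a1) / sqrt(varD)
  structure(c(list(D = D, S = S, pi_total = piTot, n = n), k),
            class = "tajimaD")
}

#' @export
print.tajimaD <- function(x, ...) {
  cat(sprintf("Tajima's D = %.5f  (S = %d, pi = %.4f, n = %d)\n",
              x$D, x$S, x$pi_total, x$n))
  invisible(x)
}

# AMOVA one-level variance components from a pairwise squared-distance
# matrix and a population factor; returns Phi_ST
phiStFromDist <- function(d2, pop) {
  N <- length(pop)
  pops <- unique(pop)
  P <- length(pops)
  ssdW <- 0
  for (p in pops) {
    idx <- which(pop == p)
    ssdW <- ssdW + sum(d2[idx, idx]) / 2 / length(idx)
  }
  ssdT <- sum(d2) / 2 / N
  ssdA <- ssdT - ssdW
  dfA <- P - 1L
  dfW <- N - P
  sigW <- ssdW / dfW
  nc <- (N - sum(table(pop)^2) / N) / dfA
  sigA <- (ssdA / dfA - sigW) / nc
  sigA / (sigA + sigW)
}

#' Pairwise population differentiation (FST and PhiST)
#'
#' Computes both a haplotype-frequency fixation index
#' `FST = (HT - HS)/HT` from within- and total gene diversities (Nei's
#' G_ST; plain diversities, so identical haplotype compositions give
#' exactly 0 and fixation for different haplotypes exactly 1), and a
#' distance-based `PhiST` from one-level AMOVA variance components on
#' pairwise sequence differences. Each is accompanied by a
#' label-shuffling permutation p-value.
#'
#' @param aln A [HapAlignment-class] carrying population labels.
#' @param pop_a,pop_b The two population labels to contrast.
#' @param n_permutations Number of label permutations (default 10000).
#' @param seed Integer seed for the permutations.
#' @return List with `fst`, `fst_p`, `phi_st`, `phi_p`, `n`.
#' @export
pairwiseFst <- function(aln, pop_a, pop_b, n_permutations = 10000L,
                        seed = 1L) {
  pops <- alnPopulations(aln)
  ids <- names(alnSequences(aln))
  sel <- ids[ids %in% names(pops)[pops %in% c(pop_a, pop_b)]]
  pop <- unname(pops[sel])
  if (sum(pop == pop_a) < 2L || sum(pop == pop_b) < 2L)
    stop("each population must have >= 2 members")
  m <- alnMatrix(aln)[sel, , drop = FALSE]
  seqs <- apply(m, 1L, paste, collapse = "")
  N <- length(sel)
  # pairwise difference matrix (used as squared distances in AMOVA)
  d2 <- matrix(0, N, N)
  for (i in seq_len(N - 1L)) for (j in (i + 1L):N) {
    a <- m[i, ]; b <- m[j, ]
    ok <- a %in% DNA_BASES & b %in% DNA_BASES
    d2[i, j] <- d2[j, i] <- sum(a[ok] != b[ok])
  }
  hapDiv <- function(x) 1 - sum((table(x) / length(x))^2)
  fstStat <- function(pp) {
    hs <- mean(c(hapDiv(seqs[pp == pop_a]), hapDiv(seqs[pp == pop_b])))
    ht <- hapDiv(seqs)
    if (ht == 0) 0 else (ht - hs) / ht
  }
  fst <- fstStat(pop)
  phi <- phiStFromDist(d2, pop)
  set.seed(seed)
  fstNull <- phiNull <- numeric(n_permutations)
  for (r in seq_len(n_permutations)) {
    pp <- sample(pop)
    fstNull[[r]] <- fstStat(pp)
    phiNull[[r]] <- phiStFromDist(d2, pp)
  }
  list(fst = fst,
       fst_p = (1 + sum(fstNull >= fst - 1e-12)) / (1 + n_permutations),
       phi_st = phi,
       phi_p = (1 + sum(phiNull >= phi - 1e-12)) / (1 + n_permutations),
       n = N)
}

#' Uncorrected p-distance between two aligned sequences
#'
#' `100 * mismatches / compared positions`. With `count_gaps = TRUE`, a
#' gap aligned to a base is a mismatch and gap-gap columns are excluded;
#' with `FALSE`, any column containing a gap is excluded. Columns with `N`
#' in either sequence are always excluded.
#'
#' @param a,b Equal-length sequence strings.
#' @param count_gaps Logical (default `TRUE`).
#' @return Percentage distance.
#' @export
pDistance <- function(a, b, count_gaps = TRUE) {
  a <- strsplit(toupper(a), "")[[1L]]
  b <- strsplit(toupper(b), "")[[1L]]
  if (length(a) != length(b)) stop("sequences must have equal length")
  keep <- a != "N" & b != "N"
  if (count_gaps) keep <- keep & !(a == "-" & b == "-")
  else keep <- keep & a != "-" & b != "-"
  if (!any(keep)) stop("no comparable positions")
  100 * sum(a[keep] != b[keep]) / sum(keep)
}

hamming <- function(a, b) sum(a != b)

# minimum spanning network over a distance matrix: connect components
# through all edges within epsilon of the minimal feasible connection cost
msnEdges <- function(D, epsilon = 0L) {
  n <- nrow(D)
  if (n == 1L) return(data.frame(i = integer(), j = integer(),
                                 w = numeric()))
  comp <- seq_len(n)
  edges <- list()
  pairs <- which(upper.tri(D), arr.ind = TRUE)
  pw <- D[upper.tri(D)]
  while (length(unique(comp)) > 1L) {
    inter <- comp[pairs[, 1L]] != comp[pairs[, 2L]]
    wmin <- min(pw[inter])
    take <- which(inter & pw <= wmin + epsilon)
    for (t in take) {
      i <- pairs[t, 1L]; j <- pairs[t, 2L]
      edges[[length(edges) + 1L]] <- c(i, j, D[i, j])
    }
    # merge components connected by the taken edges
    for (t in take) {
      ci <- comp[pairs[t, 1L]]; cj <- comp[pairs[t, 2L]]
      if (ci != cj) comp[comp == cj] <- ci
    }
  }
  e <- do.call(rbind, edges)
  data.frame(i = e[, 1L], j = e[, 2L], w = e[, 3L])
}

mstLength <- function(D) {
  n <- nrow(D)
  if (n <= 1L) return(0)
  inTree <- c(TRUE, rep(FALSE, n - 1L))
  dist <- D[1L, ]
  total <- 0
  for (step in seq_len(n - 1L)) {
    cand <- which(!inTree)
    pick <- cand[which.min(dist[cand])]
    total <- total + dist[[pick]]
    inTree[[pick]] <- TRUE
    dist <- pmin(dist, D[pick, ])
  }
  total
}

# quasi-medians of a sequence triplet: per-position majority state; when
# all three states differ the position branches (capped at maxFree
# branching positions, beyond which the first sequence's state is used)
quasiMedians <- function(a, b, c, maxFree = 6L) {
  k <- length(a)
  base <- character(k)
  free <- integer(0)
  for (s in seq_len(k)) {
    states <- c(a[[s]], b[[s]], c[[s]])
    tab <- table(states)
    if (max(tab) >= 2L) base[[s]] <- names(tab)[which.max(tab)]
    else { base[[s]] <- a[[s]]; free <- c(free, s) }
  }
  if (length(free) == 0L || length(free) > maxFree)
    return(list(base))
  out <- list()
  choices <- expand.grid(rep(list(1:3), length(free)))
  opts <- rbind(a[free], b[free], c[free])
  for (r in seq_len(nrow(choices))) {
    med <- base
    for (ci in seq_along(free))
      med[[free[[ci]]]] <- opts[choices[r, ci], ci]
    out[[length(out) + 1L]] <- med
  }
  unique(out)
}

#' Median-joining haplotype network
#'
#' Bandelt-style construction: iterate a minimum-spanning-network
#' computation over observed plus inferred median nodes, propose
#' quasi-medians of triplets that are mutually connected (within
#' `epsilon` of feasible connection cost), add candidates that reduce
#' total network length, and finally prune median nodes that no longer
#' shorten the network. Edge weights are Hamming distances.
#'
#' @param table A [HaplotypeTable-class] (haplotypes of equal length).
#' @param epsilon Non-negative integer relaxation (default 0).
#' @return An [MJNetwork-class].
#' @export
medianJoiningNetwork <- function(table, epsilon = 0L) {
  haps <- hapSequences(table)
  if (length(unique(nchar(haps))) != 1L)
    stop("haplotypes must have equal length")
  obs <- strsplit(haps, "")
  nObs <- length(obs)
  nodes <- obs                      # observed first, medians appended
  medianSeqs <- character(0)
  if (nObs > 1L) {
    repeat {
      n <- length(nodes)
      D <- matrix(0L, n, n)
      for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
        D[i, j] <- D[j, i] <- hamming(nodes[[i]], nodes[[j]])
      msn <- msnEdges(D, epsilon)
      adj <- matrix(FALSE, n, n)
      for (r in seq_len(nrow(msn)))
        adj[msn$i[[r]], msn$j[[r]]] <- adj[msn$j[[r]], msn$i[[r]]] <- TRUE
      baseLen <- mstLength(D)
      existing <- vapply(nodes, paste, character(1), collapse = "")
      best <- NULL; bestGain <- 0
      # triplets mutually connected in the MSN, lexicographic order
      for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n)) {
        if (!(i < j && j < k)) next
        if (!(adj[i, j] && adj[i, k] || adj[i, j] && adj[j, k] ||
              adj[i, k] && adj[j, k])) next
        for (med in quasiMedians(nodes[[i]], nodes[[j]], nodes[[k]])) {
          key <- paste(med, collapse = "")
          if (key %in% existing) next
          dTo <- vapply(nodes, hamming, integer(1), b = med)
          D2 <- rbind(cbind(D, dTo), c(dTo, 0L))
          gain <- baseLen - mstLength(D2)
          if (gain > bestGain + 1e-9) { bestGain <- gain; best <- med }
        }
      }
      if (is.null(best)) break
      nodes[[length(nodes) + 1L]] <- best
      medianSeqs <- c(medianSeqs, paste(best, collapse = ""))
    }
    # prune medians whose removal leaves the spanning length unchanged
    repeat {
      n <- length(nodes)
      D <- matrix(0L, n, n)
      for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
        D[i, j] <- D[j, i] <- hamming(nodes[[i]], nodes[[j]])
      full <- mstLength(D)
      dropped <- FALSE
      for (m in rev(seq_len(n))) {
        if (m <= nObs) next
        if (mstLength(D[-m, -m, drop = FALSE]) <= full + 1e-9) {
          nodes <- nodes[-m]
          medianSeqs <- medianSeqs[-(m - nObs)]
          dropped <- TRUE
          break
        }
      }
      if (!dropped) break
    }
  }
  n <- length(nodes)
  D <- matrix(0L, n, n)
  if (n > 1L)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
      D[i, j] <- D[j, i] <- hamming(nodes[[i]], nodes[[j]])
  msn <- if (n > 1L) msnEdges(D, epsilon) else
    data.frame(i = integer(), j = integer(), w = numeric())
  ids <- c(paste0("H", seq_len(nObs)),
           if (n > nObs) paste0("M", seq_len(n - nObs)) else character(0))
  nodesDf <- data.frame(
    id = ids,
    sequence = vapply(nodes, paste, character(1), collapse = ""),
    kind = c(rep("observed", nObs), rep("median", n - nObs)),
    count = c(hapCounts(table), rep(0L, n - nObs)))
  edgesDf <- data.frame(from = ids[msn$i], to = ids[msn$j], weight = msn$w)
  new("MJNetwork", nodes = nodesDf, edges = edgesDf)
}

#' Sliding-window nucleotide diversity along an alignment
#'
#' Windows of `window` sites advancing by `step`; the final partial
#' window is dropped. Pi is computed per window with the pairwise
#' exclusion rule of [nucleotideDiversity()]; a window in which some pair
#' has no comparable sites yields `NA`.
#'
#' @param aln A [HapAlignment-class].
#' @param window Window size in sites (`<= alnLength(aln)`).
#' @param step Step size (> 0).
#' @return Data frame with `start`, `end`, `pi`.
#' @export
slidingWindowDiversity <- function(aln, window, step) {
  if (step <= 0L) stop("step must be > 0")
  L <- alnLength(aln)
  if (window > L) stop("window exceeds alignment length")
  seqs <- alnSequences(aln)
  starts <- seq(1L, L - window + 1L, by = step)
  out <- lapply(starts, function(s) {
    sub <- HapAlignment(stats::setNames(substr(seqs, s, s + window - 1L),
                                        names(seqs)))
    p <- tryCatch(nucleotideDiversity(sub), error = function(e) NA_real_)
    data.frame(start = s, end = s + window - 1L, pi = p)
  })
  do.call(rbind, out)
}
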