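#' Simulation configuration for the synthetic cox1/pool generators
#'
#' Bundles the parameters of the coalescent haplotype generator and the
#' two-stage pool-sequencing sampler. The defaults are the study
#' conditions the package's analyses assume: a per-site scaled mutation
#' rate giving roughly 2% nucleotide diversity, 24 individually sequenced
#' haplotypes, a pool of 80 individuals sequenced to a few-hundred-fold
#' coverage, and a small uniform sequencing-error rate.
#'
#' @param theta_per_site Scaled mutation rate per site (expected
#'   nucleotide diversity under neutrality). Default 0.02.
#' @param n_haplotypes Number of sampled haplotypes (coalescent tips).
#' @param pool_size Number of pooled individuals `n`. Default 80.
#' @param mean_depth Mean per-site read depth of the pool. Default 300.
#' @param read_length Nominal read length (metadata only). Default 150.
#' @param error_rate Per-base uniform substitution error in `[0,1)`.
#' @param seed Integer seed; fully determines every simulator's output.
#' @return A list with class `simConfig`.
#' @export
simConfig <- function(theta_per_site = 0.02, n_haplotypes = 24L,
                      pool_size = 80L, mean_depth = 300, read_length = 150L,
                      error_rate = 0.001, seed = 1L) {
  stopifnot(is.finite(theta_per_site), theta_per_site >= 0,
            n_haplotypes >= 2L, pool_size >= 1L, mean_depth > 0,
            error_rate >= 0, error_rate < 1)
  structure(list(theta_per_site = theta_per_site,
                 n_haplotypes = as.integer(n_haplotypes),
                 pool_size = as.integer(pool_size), mean_depth = mean_depth,
                 read_length = as.integer(read_length),
                 error_rate = error_rate, seed = as.integer(seed)),
            class = "simConfig")
}

# Kingman coalescent genealogy for n tips: returns per-edge branch lengths
# (coalescent units of 2N generations) and the tip set below each edge.
coalescentTree <- function(n) {
  active <- as.list(seq_len(n))          # tip sets of active lineages
  lens <- numeric(0); sets <- list()
  heights <- rep(0, n)                   # current height of each active lineage
  t <- 0
  while (length(active) > 1L) {
    j <- length(active)
    t <- t + rexp(1L, rate = j * (j - 1) / 2)
    pick <- sample.int(j, 2L)
    for (p in pick) {                    # close the two coalescing edges
      lens <- c(lens, t - heights[[p]])
      sets <- c(sets, active[p])
    }
    merged <- sort(c(active[[pick[1L]]], active[[pick[2L]]]))
    active <- c(active[-pick], list(merged))
    heights <- c(heights[-pick], t)
  }
  list(lengths = lens, tipsets = sets)
}

#' Simulate aligned haplotypes under the neutral coalescent
#'
#' Draws a Kingman genealogy for `n_haplotypes` tips and places mutations
#' on it as a Poisson process with rate `theta_per_site/2` per site per
#' unit branch length, under the infinite-sites model (a site already
#' mutated is not reused; colliding mutations are re-placed). Each
#' mutation substitutes a uniformly chosen different base in all
#' descendant tips.
#'
#' @param reference Reference nucleotide string (length >= 100).
#' @param config A [simConfig()].
#' @return List with `sequences` (named character vector, one per tip),
#'   `sft` (data frame of true segregating sites: `site`, `derived_count`,
#'   `ancestral`, `derived`), and `tree_length`.
#' @examples
#' ref <- randomReference(200, seed = 7)
#' h <- simulateHaplotypes(ref, simConfig(n_haplotypes = 6, seed = 7))
#' nrow(h$sft)
#' @export
simulateHaplotypes <- function(reference, config) {
  reference <- toupper(reference)
  L <- nchar(reference)
  if (L < 100L) stop("reference length must be >= 100")
  set.seed(config$seed)
  n <- config$n_haplotypes
  tree <- coalescentTree(n)
  total <- sum(tree$lengths)
  nMut <- rpois(1L, config$theta_per_site / 2 * L * total)
  if (nMut > L)
    stop("segregating sites would exceed reference length; ",
         "use a smaller theta_per_site")
  refChars <- strsplit(reference, "")[[1L]]
  seqs <- matrix(rep(refChars, n), nrow = n, byrow = TRUE)
  sites <- integer(0)
  sft <- list()
  if (nMut > 0L) {
    edges <- sample.int(length(tree$lengths), nMut, replace = TRUE,
                        prob = tree$lengths)
    for (m in seq_len(nMut)) {
      repeat {                           # infinite sites: no site reuse
        s <- sample.int(L, 1L)
        if (!(s %in% sites)) break
      }
      sites <- c(sites, s)
      anc <- refChars[[s]]
      der <- sample(setdiff(DNA_BASES, anc), 1L)
      tips <- tree$tipsets[[edges[[m]]]]
      seqs[tips, s] <- der
      sft[[m]] <- data.frame(site = s, derived_count = length(tips),
                             ancestral = anc, derived = der)
    }
  }
  sequences <- stats::setNames(apply(seqs, 1L, paste, collapse = ""),
                               paste0("hap", seq_len(n)))
  sftdf <- if (length(sft)) {
    d <- do.call(rbind, sft); d[order(d$site), , drop = FALSE]
  } else data.frame(site = integer(), derived_count = integer(),
                    ancestral = character(), derived = character())
  rownames(sftdf) <- NULL
  list(sequences = sequences, sft = sftdf, tree_length = total)
}

#' Random reference sequence
#'
#' @param length Sequence length.
#' @param gc Target GC content in `[0,1]` (default 0.35, AT-rich as in
#'   flatworm mitogenomes).
#' @param seed Optional integer seed.
#' @return A nucleotide string.
#' @export
randomReference <- function(length, gc = 0.35, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(DNA_BASES, length, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Simulate pooled sequencing of a haplotype sample
#'
#' Two-stage sampling: stage 1 draws `pool_size` haplotype copies
#' uniformly with replacement from `haplotypes` (or uses supplied
#' `frequencies`, or uses the haplotypes as-is when
#' `resample = FALSE`); stage 2 draws a per-site depth from
#' Poisson(`mean_depth`) and allocates reads multinomially over the pooled
#' base frequencies. Each emitted base is flipped to a uniformly chosen
#' different base with probability `error_rate`.
#'
#' @param haplotypes Named character vector of equal-length aligned
#'   sequences (gap-free).
#' @param config A [simConfig()]; uses `pool_size`, `mean_depth`,
#'   `error_rate`, `seed`.
#' @param frequencies Optional numeric vector of haplotype frequencies
#'   (stage-1 copies are drawn multinomially from these).
#' @param resample If `FALSE`, the supplied haplotypes are the pool (one
#'   copy each) and `pool_size` is taken as their number.
#' @return List with `sites` (data frame `chrom`, `pos`, `ref`, `depth`,
#'   `A`, `C`, `G`, `T`), `true_freqs` (data frame `pos`, base-frequency
#'   columns and `derived_freq` = copies carrying the non-reference
#'   majority-complement base / pool size), and `pool_counts` (copies per
#'   haplotype).
#' @export
simulatePool <- function(haplotypes, config, frequencies = NULL,
                         resample = TRUE) {
  if (length(haplotypes) == 0L) stop("empty haplotype list")
  L <- nchar(haplotypes[[1L]])
  if (any(nchar(haplotypes) != L)) stop("haplotypes must be aligned")
  set.seed(config$seed + 1L)             # distinct stream from the coalescent
  nh <- length(haplotypes)
  if (!resample) {
    copies <- rep(1L, nh); poolN <- nh
  } else {
    poolN <- config$pool_size
    pr <- if (is.null(frequencies)) rep(1 / nh, nh) else frequencies / sum(frequencies)
    copies <- as.integer(rmultinom(1L, poolN, pr))
  }
  hapMat <- do.call(rbind, strsplit(haplotypes, ""))   # nh x L
  # pooled base frequencies per site
  baseFreq <- matrix(0, 4L, L, dimnames = list(DNA_BASES, NULL))
  for (b in DNA_BASES)
    baseFreq[b, ] <- colSums((hapMat == b) * copies) / poolN
  depth <- rpois(L, config$mean_depth)
  counts <- matrix(0L, 4L, L, dimnames = list(DNA_BASES, NULL))
  mono <- colSums(baseFreq == 1) == 1L   # monomorphic fast path
  for (s in which(mono)) {
    b <- DNA_BASES[baseFreq[, s] == 1]
    counts[b, s] <- depth[[s]]
  }
  for (s in which(!mono))
    counts[, s] <- rmultinom(1L, depth[[s]], baseFreq[, s])
  e <- config$error_rate
  if (e > 0) {
    for (s in seq_len(L)) {
      for (b in DNA_BASES) {
        c0 <- counts[b, s]
        if (c0 == 0L) next
        flips <- rbinom(1L, c0, e)
        if (flips > 0L) {
          counts[b, s] <- counts[b, s] - flips
          dest <- sample(setdiff(DNA_BASES, b), flips, replace = TRUE)
          for (d in dest) counts[d, s] <- counts[d, s] + 1L
        }
      }
    }
  }
  ref <- apply(baseFreq, 2L, function(f) DNA_BASES[which.max(f)])
  seg <- which(colSums(baseFreq > 0) > 1L)
  tf <- data.frame(pos = seg,
                   t(baseFreq[, seg, drop = FALSE]))
  names(tf) <- c("pos", DNA_BASES)
  tf$derived_freq <- vapply(seq_along(seg), function(i) {
    f <- baseFreq[, seg[[i]]]
    sum(f[DNA_BASES != ref[[seg[[i]]]]])
  }, numeric(1))
  sites <- data.frame(chrom = "sim", pos = seq_len(L), ref = ref,
                      depth = depth, A = counts["A", ], C = counts["C", ],
                      G = counts["G", ], T = counts["T", ])
  rownames(sites) <- NULL
  list(sites = sites, true_freqs = tf,
       pool_counts = stats::setNames(copies, names(haplotypes)))
}

#' Specify one element of a synthetic mitogenome layout
#'
#' @param name Feature name.
#' @param kind One of `"protein"`, `"tRNA"`, `"rRNA"`, `"NCR"`,
#'   `"repeat"`.
#' @param length Feature length in bp (for `"repeat"`, derived from motif
#'   and copies when omitted).
#' @param start_codon,stop_codon Codons for protein genes; the stop may be
#'   abbreviated `"T"` or `"TA"` (completed to TAA by polyadenylation).
#' @param gc Target GC content for NCR/rRNA/tRNA filler (default 0.3).
#' @param motif_length,copies Repeat-region motif length and copy number
#'   (copies may be fractional).
#' @param anticodon Optional anticodon for tRNA features.
#' @return A list describing the element.
#' @export
layoutElement <- function(name, kind, length = NULL, start_codon = "ATG",
                          stop_codon = "TAA", gc = 0.3, motif_length = NULL,
                          copies = NULL, anticodon = NA_character_) {
  list(name = name, kind = kind, length = length, start_codon = start_codon,
       stop_codon = stop_codon, gc = gc, motif_length = motif_length,
       copies = copies, anticodon = anticodon)
}

# codons that are not canonical stops under the flatworm code (TAA/TAG)
nonStopCodons <- function() {
  all3 <- as.vector(outer(outer(DNA_BASES, DNA_BASES, paste0), DNA_BASES,
                          paste0))
  setdiff(all3, c("TAA", "TAG"))
}

#' Simulate a circular mitogenome realizing a declared layout
#'
#' Builds a circular sequence from an ordered list of [layoutElement()]s:
#' protein-coding genes (with declared start codons, canonical or
#' abbreviated stops, and no internal in-frame canonical stop), tRNA/rRNA
#' filler, AT-rich non-coding regions with a target GC, and a tandem
#' repeat region. Returns the genome together with the truth annotation
#' used by annotation-recovery tests.
#'
#' @param layout List of [layoutElement()]s, in genome order.
#' @param seed Integer seed.
#' @param rotate Integer offset: the final sequence is rotated so that
#'   position `rotate + 1` becomes position 1, producing features that
#'   wrap the origin (default 0).
#' @param repeat_mutation Per-base substitution probability applied
#'   independently to each repeat copy (default 0).
#' @return List with `genome` (a [CircularGenome-class]) and `features`
#'   (truth data frame: `name`, `kind`, `start`, `end`, `length`,
#'   `start_codon`, `stop_codon`, `anticodon`, `gc`).
#' @export
simulateMitogenome <- function(layout, seed = 1L, rotate = 0L,
                               repeat_mutation = 0) {
  set.seed(seed)
  mid <- nonStopCodons()
  seqParts <- character(0)
  feats <- list()
  pos <- 1L
  for (el in layout) {
    if (el$kind == "protein") {
      stopLen <- nchar(el$stop_codon)
      if (!el$stop_codon %in% c("TAA", "TAG", "TA", "T"))
        stop("unsupported stop codon ", el$stop_codon)
      nmid <- (el$length - 3L - stopLen) / 3
      if (nmid != floor(nmid) || nmid < 1)
        stop("protein length ", el$length, " incompatible with start/stop (",
             el$name, "); need length = 3 + 3k + nchar(stop)")
      s <- paste0(el$start_codon,
                  paste(sample(mid, nmid, replace = TRUE), collapse = ""),
                  el$stop_codon)
    } else if (el$kind == "repeat") {
      motif <- randomReference(el$motif_length, gc = el$gc)
      full <- floor(el$copies)
      copies <- replicate(full, motif)
      if (repeat_mutation > 0) {
        copies <- vapply(copies, function(cp) {
          ch <- strsplit(cp, "")[[1L]]
          hit <- runif(length(ch)) < repeat_mutation
          ch[hit] <- vapply(ch[hit], function(b)
            sample(setdiff(DNA_BASES, b), 1L), character(1))
          paste(ch, collapse = "")
        }, character(1))
      }
      partial <- round((el$copies - full) * el$motif_length)
      s <- paste0(paste(copies, collapse = ""),
                  if (partial > 0) substr(motif, 1L, partial) else "")
      el$length <- nchar(s)
    } else {                             # tRNA / rRNA / NCR filler
      s <- randomReference(el$length, gc = el$gc)
    }
    seqParts <- c(seqParts, s)
    feats[[length(feats) + 1L]] <- data.frame(
      name = el$name, kind = el$kind, start = pos,
      end = pos + nchar(s) - 1L, length = nchar(s),
      start_codon = if (el$kind == "protein") el$start_codon else NA_character_,
      stop_codon = if (el$kind == "protein") el$stop_codon else NA_character_,
      anticodon = el$anticodon)
    pos <- pos + nchar(s)
  }
  genomeSeq <- paste(seqParts, collapse = "")
  L <- nchar(genomeSeq)
  features <- do.call(rbind, feats)
  if (rotate > 0L) {
    rotate <- rotate %% L
    genomeSeq <- paste0(substr(genomeSeq, rotate + 1L, L),
                        substr(genomeSeq, 1L, rotate))
    shift <- function(p) ((p - rotate - 1L) %% L) + 1L
    features$start <- shift(features$start)
    features$end <- shift(features$end)
  }
  genome <- CircularGenome(genomeSeq)
  features$gc <- vapply(seq_len(nrow(features)), function(i)
    gcContent(genome, features$start[[i]], features$end[[i]]), numeric(1))
  list(genome = genome, features = features)
}

#' Default synthetic mitogenome layout
#'
#' A compact flatworm-style layout: protein genes with canonical and
#' alternative (ATT, GTG) starts, one abbreviated `TA` stop abutting a
#' tRNA, AT-rich non-coding regions and a 90 bp x 11 tandem repeat.
#'
#' @return List of [layoutElement()]s.
#' @export
defaultMitogenomeLayout <- function() {
  list(
    layoutElement("cox1", "protein", length = 1554, start_codon = "ATG",
                  stop_codon = "TAA"),
    layoutElement("trnT", "tRNA", length = 66, anticodon = "TGT"),
    layoutElement("NCR1", "NCR", length = 1096, gc = 0.318),
    layoutElement("rrnL", "rRNA", length = 951),
    layoutElement("nad1", "protein", length = 876, start_codon = "ATT",
                  stop_codon = "TAA"),
    layoutElement("nad2", "protein", length = 824, start_codon = "ATG",
                  stop_codon = "TA"),
    layoutElement("trnV", "tRNA", length = 62, anticodon = "TAC"),
    layoutElement("NCR2", "NCR", length = 354, gc = 0.211),
    layoutElement("nad3", "protein", length = 348, start_codon = "GTG",
                  stop_codon = "TAG"),
    layoutElement("repeat", "repeat", motif_length = 90, copies = 11,
                  gc = 0.25),
    layoutElement("trnG", "tRNA", length = 62, anticodon = "TTC"))
}

#' Simulate landmark configurations with group and allometric structure
#'
#' Each specimen is the mean shape plus its group offset, plus an
#' allometric shape change proportional to centred log centroid size,
#' plus isotropic Gaussian landmark noise; the configuration is then
#' randomly rotated, translated and scaled so that superimposition is
#' non-trivial.
#'
#' @param mean_shape `k x 2` matrix.
#' @param group_offsets List of `k x 2` shape-space offset matrices, one
#'   per group (zeros for no group effect).
#' @param allometry_slope `k x 2` matrix of shape change per unit of
#'   centred log size, or the scalar 0 for no allometry.
#' @param noise_sd Isotropic landmark noise standard deviation (>= 0).
#' @param sizes Integer vector of specimens per group.
#' @param seed Integer seed.
#' @param roles Optional per-landmark roles (`"fixed"`/`"semi"`).
#' @return A [ShapeDataset-class] (raw, unsuperimposed).
#' @export
simulateLandmarks <- function(mean_shape, group_offsets, allometry_slope = 0,
                              noise_sd = 0.01, sizes, seed = 1L,
                              roles = NULL) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  k <- nrow(mean_shape)
  if (is.numeric(allometry_slope) && length(allometry_slope) == 1L)
    allometry_slope <- matrix(allometry_slope, k, 2L)
  set.seed(seed)
  n <- sum(sizes)
  groups <- rep(paste0("g", seq_along(sizes)), sizes)
  logsize <- rnorm(n, 0, 0.3)
  logsize <- logsize - mean(logsize)
  coords <- array(NA_real_, c(k, 2L, n))
  idx <- 0L
  for (g in seq_along(sizes)) {
    for (i in seq_len(sizes[[g]])) {
      idx <- idx + 1L
      shp <- mean_shape + group_offsets[[g]] +
        allometry_slope * logsize[[idx]] +
        matrix(rnorm(2L * k, 0, noise_sd), k, 2L)
      th <- runif(1L, 0, 2 * pi)
      R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L, 2L)
      shp <- shp %*% R
      shp <- shp * exp(logsize[[idx]])
      shp <- sweep(shp, 2L, runif(2L, -5, 5), "+")
      coords[, , idx] <- shp
    }
  }
  ShapeDataset(coords, roles = roles, ids = paste0("s", seq_len(n)),
               groups = groups)
}
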