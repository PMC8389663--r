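# Independent brute-force oracles used to validate the package's
# estimators. These deliberately share no code with the implementation:
# plain double loops straight from the textbook definitions.

DNA <- c("A", "C", "G", "T")

randomAlignment <- function(n, L, states = DNA, withPop = FALSE) {
  seqs <- vapply(seq_len(n), function(i)
    paste(sample(states, L, replace = TRUE), collapse = ""), character(1))
  names(seqs) <- paste0("s", seq_len(n))
  pops <- if (withPop)
    stats::setNames(sample(c("A", "B"), n, replace = TRUE), names(seqs))
  else character(0)
  HapAlignment(seqs, populations = pops)
}

# correlated random alignment: mutate copies of one ancestor so that
# haplotype structure is non-trivial
mutatedAlignment <- function(n, L, nMut = 5L, states = DNA) {
  anc <- sample(states, L, replace = TRUE)
  seqs <- character(n)
  for (i in seq_len(n)) {
    s <- anc
    hits <- sample.int(L, sample.int(nMut, 1L))
    s[hits] <- sample(states, length(hits), replace = TRUE)
    seqs[[i]] <- paste(s, collapse = "")
  }
  names(seqs) <- paste0("s", seq_len(n))
  HapAlignment(seqs)
}

bruteForcePi <- function(aln) {
  m <- do.call(rbind, strsplit(alnSequences(aln), ""))
  n <- nrow(m)
  acc <- 0; np <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    np <- np + 1
    num <- 0; den <- 0
    for (s in seq_len(ncol(m))) {
      a <- m[i, s]; b <- m[j, s]
      if (a %in% DNA && b %in% DNA) {
        den <- den + 1
        if (a != b) num <- num + 1
      }
    }
    acc <- acc + num / den
  }
  acc / np
}

bruteForceTajima <- function(aln) {
  m <- do.call(rbind, strsplit(alnSequences(aln), ""))
  n <- nrow(m)
  S <- 0
  for (s in seq_len(ncol(m))) {
    st <- unique(m[, s]); st <- st[st %in% DNA]
    if (length(st) >= 2) S <- S + 1
  }
  piTot <- 0; np <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    np <- np + 1
    for (s in seq_len(ncol(m))) {
      a <- m[i, s]; b <- m[j, s]
      if (a %in% DNA && b %in% DNA && a != b) piTot <- piTot + 1
    }
  }
  piTot <- piTot / np
  a1 <- sum(1 / (1:(n - 1))); a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  (piTot - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

bruteForcePhiSt <- function(aln, popA, popB) {
  pops <- alnPopulations(aln)
  ids <- names(alnSequences(aln))
  sel <- ids[pops[ids] %in% c(popA, popB)]
  m <- do.call(rbind, strsplit(alnSequences(aln)[sel], ""))
  pop <- pops[sel]
  N <- length(sel)
  d2 <- matrix(0, N, N)
  for (i in seq_len(N - 1)) for (j in (i + 1):N)
    d2[i, j] <- d2[j, i] <- sum(m[i, ] != m[j, ])
  ssdW <- 0
  for (p in unique(pop)) {
    idx <- which(pop == p)
    s <- 0
    for (i in idx) for (j in idx) s <- s + d2[i, j]
    ssdW <- ssdW + s / (2 * length(idx))
  }
  ssdT <- sum(d2) / (2 * N)
  P <- length(unique(pop))
  sigW <- (ssdW) / (N - P)
  nc <- (N - sum(table(pop)^2) / N) / (P - 1)
  sigA <- ((ssdT - ssdW) / (P - 1) - sigW) / nc
  sigA / (sigA + sigW)
}

bruteForceCollapse <- function(aln) {
  seqs <- alnSequences(aln)
  n <- length(seqs)
  assigned <- integer(n); grp <- 0
  for (i in seq_len(n)) {
    if (assigned[[i]] > 0) next
    grp <- grp + 1
    assigned[[i]] <- grp
    if (i < n) for (j in (i + 1):n)
      if (assigned[[j]] == 0 && identical(seqs[[i]], seqs[[j]]))
        assigned[[j]] <- grp
  }
  split(names(seqs), assigned)
}

# independent pileup read-base decoder: regex-free character machine
# written from the format description
oracleDecode <- function(bases, ref) {
  counts <- c(A = 0, C = 0, G = 0, T = 0)
  v <- utf8ToInt(bases)
  i <- 1
  while (i <= length(v)) {
    ch <- intToUtf8(v[[i]])
    if (ch == "^") { i <- i + 2; next }
    if (ch == "$") { i <- i + 1; next }
    if (ch == "+" || ch == "-") {
      j <- i + 1; num <- ""
      while (j <= length(v) && intToUtf8(v[[j]]) %in% as.character(0:9)) {
        num <- paste0(num, intToUtf8(v[[j]])); j <- j + 1
      }
      i <- j + as.integer(num); next
    }
    if (ch %in% c(".", ",")) counts[[ref]] <- counts[[ref]] + 1
    else if (toupper(ch) %in% names(counts))
      counts[[toupper(ch)]] <- counts[[toupper(ch)]] + 1
    i <- i + 1
  }
  counts
}

randomPileupLine <- function(pos) {
  ref <- sample(DNA, 1)
  n <- sample.int(15, 1)
  toks <- character(n)
  for (t in seq_len(n)) {
    r <- runif(1)
    base <- if (r < 0.6) sample(c(".", ","), 1)
            else sample(c(DNA, tolower(DNA), "N", "*"), 1)
    pre <- if (runif(1) < 0.15) paste0("^", intToUtf8(sample(33:90, 1))) else ""
    post <- if (runif(1) < 0.1) "$" else ""
    indel <- if (runif(1) < 0.15) {
      len <- sample.int(4, 1)
      paste0(sample(c("+", "-"), 1), len,
             paste(sample(DNA, len, replace = TRUE), collapse = ""))
    } else ""
    toks[[t]] <- paste0(pre, base, post, indel)
  }
  bases <- paste(toks, collapse = "")
  list(line = paste("ref", pos, ref, n, bases, strrep("I", n), sep = "\t"),
       bases = bases, ref = ref, depth = n)
}

circleShape <- function(k) {
  th <- seq(0, 2 * pi, length.out = k + 1)[-(k + 1)]
  cbind(cos(th), sin(th))
}
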