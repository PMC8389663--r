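test_that("circular span arithmetic matches the annotation convention", {
  expect_equal(spanLength(536, 1181, 15575), 646)
  expect_equal(spanLength(14965, 426, 15575), 1037)
  expect_equal(spanLength(7, 7, 100), 1)

  g <- CircularGenome(randomReference(60, seed = 1))
  expect_equal(nchar(extractRegion(g, 10, 20)), 11L)
  expect_equal(extractRegion(g, 55, 5),
               paste0(substr(genomeSequence(g), 55, 60),
                      substr(genomeSequence(g), 1, 5)))
  lin <- CircularGenome(randomReference(60, seed = 1), circular = FALSE)
  expect_error(extractRegion(lin, 55, 5), "non-circular")
  expect_error(extractRegion(g, 0, 5), "within")
})

test_that("span length formula holds exhaustively on a small circle", {
  L <- 40L
  g <- CircularGenome(randomReference(L, seed = 2))
  for (s in seq_len(L)) for (e in seq_len(L)) {
    expect_equal(nchar(extractRegion(g, s, e)), spanLength(s, e, L))
  }
})

test_that("translation uses the flatworm code with abbreviated tails", {
  expect_equal(translateMito("TGA"), "W")
  expect_equal(translateMito("AAA"), "N")
  expect_equal(translateMito("AGA"), "S")
  expect_equal(translateMito("AGG"), "S")
  expect_equal(translateMito(""), "")
  expect_equal(translateMito("ATGT"), "M*")     # abbreviated "T"
  expect_equal(translateMito("ATGTA"), "M*")    # abbreviated "TA"
  expect_error(translateMito("ATGC"), "abbreviated")
  expect_warning(out <- translateMito("ATGNNN"), "X")
  expect_equal(out, "MX")
})

test_that("ORF scanning recovers constructed genes exactly", {
  lay <- list(
    layoutElement("gA", "protein", length = 333, start_codon = "ATT",
                  stop_codon = "TAA"),
    layoutElement("spacer", "NCR", length = 200, gc = 0.2),
    layoutElement("gB", "protein", length = 311, start_codon = "ATG",
                  stop_codon = "TA"),
    layoutElement("t1", "tRNA", length = 62))
  mito <- simulateMitogenome(lay, seed = 33)
  f <- mito$features
  bnd <- f$start[f$name == "t1"]
  orfs <- scanOrfs(mito$genome, min_length = 150, boundaries = bnd)
  gA <- f[f$name == "gA", ]
  expect_true(any(orfs$start == gA$start & orfs$end == gA$end &
                    orfs$strand == "+" & orfs$start_codon == "ATT"))
  gB <- f[f$name == "gB", ]
  hit <- orfs$start == gB$start & orfs$end == gB$end & orfs$strand == "+"
  expect_true(any(hit))
  expect_equal(orfs$stop_codon[hit][[1]], "TA")

  # no allowed start at all
  noStart <- CircularGenome(strrep("C", 300))
  expect_equal(nrow(scanOrfs(noStart, min_length = 30)), 0L)
  expect_error(scanOrfs(noStart, min_length = 2), ">= 3")
})

test_that("ORF recovery is exact across random layouts", {
  set.seed(134)
  for (rep in 1:25) {
    nGenes <- sample(2:4, 1)
    lay <- list()
    for (gi in seq_len(nGenes)) {
      lay[[length(lay) + 1]] <- layoutElement(
        paste0("g", gi), "protein",
        length = 3 * sample(60:200, 1) + 3 + 3,
        start_codon = sample(c("ATG", "GTG", "ATT"), 1),
        stop_codon = sample(c("TAA", "TAG"), 1))
      lay[[length(lay) + 1]] <- layoutElement(
        paste0("s", gi), "NCR", length = sample(60:150, 1), gc = 0.3)
    }
    mito <- simulateMitogenome(lay, seed = 1000 + rep,
                               rotate = sample(0:500, 1))
    orfs <- scanOrfs(mito$genome, min_length = 150)
    prot <- mito$features[mito$features$kind == "protein", ]
    for (r in seq_len(nrow(prot))) {
      expect_true(any(orfs$start == prot$start[[r]] &
                        orfs$end == prot$end[[r]] &
                        orfs$strand == "+"),
                  info = paste("rep", rep, prot$name[[r]]))
    }
  }
})

test_that("GC and AT content are complementary and exact", {
  expect_equal(gcContent("ATAT"), 0)
  expect_equal(gcContent("GGCC"), 100)
  g <- CircularGenome(randomReference(500, gc = 0.4, seed = 3))
  expect_equal(gcContent(g) + atContent(g), 100)
  expect_equal(gcContent(g, 490, 20),
               gcContent(extractRegion(g, 490, 20)))
})

test_that("tandem repeat detection recovers constructed arrays", {
  set.seed(135)
  flank1 <- randomReference(400, seed = 4)
  flank2 <- randomReference(400, seed = 5)
  motif <- "ACGT"
  g <- CircularGenome(paste0(flank1, strrep(motif, 5), flank2),
                      circular = FALSE)
  reps <- findTandemRepeats(g, min_period = 2, max_period = 30)
  hit <- reps[reps$period == 4 & reps$copies >= 4.5, , drop = FALSE]
  expect_equal(nrow(hit), 1L)
  expect_lte(abs(hit$start - 401), 4)
  expect_equal(hit$copies, 5.0, tolerance = 0.11)

  # 90 bp motif x 11 with ~2% mutation per copy
  lay <- list(layoutElement("f", "NCR", length = 2000, gc = 0.3),
              layoutElement("rep", "repeat", motif_length = 90,
                            copies = 11, gc = 0.3),
              layoutElement("f2", "NCR", length = 2000, gc = 0.3))
  mito <- simulateMitogenome(lay, seed = 44, repeat_mutation = 0.02)
  truth <- mito$features[mito$features$name == "rep", ]
  det <- findTandemRepeats(mito$genome, min_period = 60, max_period = 120)
  expect_gte(nrow(det), 1L)
  best <- det[which.max(det$copies), ]
  expect_lte(abs(best$period - 90), 2)
  expect_gte(best$copies, 10)
  # detected span overlaps the truth span
  expect_lt(max(best$start, truth$start), min(best$end, truth$end))
})

test_that("random sequence yields no long high-copy arrays", {
  hits <- vapply(1:50, function(seed) {
    s <- randomReference(10000, gc = 0.5, seed = 7000 + seed)
    det <- findTandemRepeats(CircularGenome(s, circular = FALSE),
                             min_period = 20, max_period = 60,
                             min_copies = 3)
    nrow(det)
  }, numeric(1))
  expect_equal(sum(hits), 0)
})

test_that("non-coding regions are located with wrap awareness", {
  lay <- list(layoutElement("gA", "protein", length = 306),
              layoutElement("gapA", "NCR", length = 354, gc = 0.211),
              layoutElement("gB", "protein", length = 306),
              layoutElement("gapB", "NCR", length = 120, gc = 0.3))
  mito <- simulateMitogenome(lay, seed = 55)
  f <- mito$features
  ncrs <- locateNcrs(f[f$kind == "protein", ], mito$genome,
                     min_length = 50)
  expect_equal(nrow(ncrs), 2L)
  gapA <- ncrs[ncrs$length == 354, ]
  expect_equal(gapA$gc, f$gc[f$name == "gapA"])

  # rotate so one gap wraps the origin
  mito2 <- simulateMitogenome(lay, seed = 55, rotate = 306 + 354 + 306 + 60)
  f2 <- mito2$features
  ncrs2 <- locateNcrs(f2[f2$kind == "protein", ], mito2$genome,
                      min_length = 50)
  wrapped <- ncrs2[ncrs2$end < ncrs2$start, ]
  expect_equal(nrow(wrapped), 1L)
  expect_equal(wrapped$length, 120L)

  # adjacent features leave no NCR
  lay3 <- list(layoutElement("gA", "protein", length = 306),
               layoutElement("gB", "protein", length = 306))
  mito3 <- simulateMitogenome(lay3, seed = 56)
  expect_equal(nrow(locateNcrs(mito3$features, mito3$genome)), 0L)
})
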