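#' End-to-end synthetic demonstration pipeline
#'
#' Chains the whole framework on one seed: coalescent haplotype
#' simulation, individual-based population genetics, two-stage pool
#' simulation and pool-corrected windowed statistics, Sanger-vs-pool SNP
#' concordance, mitogenome simulation and annotation recovery, landmark
#' simulation with Procrustes analysis, and infection descriptors.
#' Cross-module invariants are asserted along the way; all outputs are
#' written as plain-text tables under `output_dir` together with a JSON
#' manifest recording the configuration (a second run with the same seed
#' produces byte-identical statistic tables).
#'
#' @param seed Integer seed driving every stochastic stage.
#' @param output_dir Output directory (created if needed).
#' @param theta_per_site,n_haplotypes,pool_size,mean_depth Study
#'   conditions; defaults are the package's standard synthetic scenario.
#' @return Invisibly, a list with the stage results and the manifest.
#' @export
runDemo <- function(seed = 1L, output_dir = tempfile("mitopool_demo"),
                    theta_per_site = 0.02, n_haplotypes = 24L,
                    pool_size = 80L, mean_depth = 300) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  # one coalescent sample for the whole metapopulation: the first
  # n_haplotypes tips are sequenced individually, the rest are pooled
  cfg <- simConfig(theta_per_site = theta_per_site,
                   n_haplotypes = n_haplotypes + pool_size,
                   pool_size = pool_size, mean_depth = mean_depth,
                   seed = seed)
  ref <- randomReference(392L, seed = seed)
  all <- simulateHaplotypes(ref, cfg)
  hap <- list(sequences = all$sequences[seq_len(n_haplotypes)])

  # individual-based stage
  writeFasta(hap$sequences, file.path(output_dir, "haplotypes.fasta"))
  aln <- HapAlignment(hap$sequences)
  tab <- collapseHaplotypes(aln)
  stats <- data.frame(
    n = sampleSize(aln), L = alnLength(aln),
    n_haplotypes = length(hapSequences(tab)),
    polymorphic_sites = nPolymorphicSites(tab),
    haplotype_diversity = haplotypeDiversity(tab),
    nucleotide_diversity = nucleotideDiversity(aln),
    tajimas_d = if (nPolymorphicSites(tab) >= 1L) tajimasD(aln)$D
                else NA_real_)
  stopifnot(stats$haplotype_diversity >= 0, stats$haplotype_diversity <= 1,
            stats$nucleotide_diversity >= 0,
            stats$nucleotide_diversity <= 1)
  write.table(stats, file.path(output_dir, "popgen_stats.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  net <- medianJoiningNetwork(tab)
  write.table(networkEdges(net), file.path(output_dir, "mj_edges.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  # pooled stage: the remaining tips of the same coalescent sample
  poolHaps <- all$sequences[n_haplotypes + seq_len(pool_size)]
  pool <- simulatePool(poolHaps, cfg, resample = FALSE)
  writePileup(pool$sites, file.path(output_dir, "pool.pileup"))
  pcfg <- poolConfig(pool_size = pool_size, window = 392L, step = 2L)
  wstats <- windowedStats(pool$sites, pcfg, ref_length = 392L)
  stopifnot(all(wstats$theta_pi >= 0, na.rm = TRUE),
            all(wstats$theta_w >= 0, na.rm = TRUE))
  write.table(wstats, file.path(output_dir, "pool_windows.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  # concordance stage
  indSnps <- individualAlleleFrequencies(aln)
  called <- callSnps(pool$sites, pcfg)
  poolSnps <- data.frame(pos = called$pos[called$is_snp],
                         minor = called$minor[called$is_snp],
                         freq = called$maf[called$is_snp])
  comp <- compareSnpSets(indSnps, poolSnps, pool_size = pool_size,
                         individual_n = sampleSize(aln))
  stopifnot(nrow(comp$shared) + nrow(comp$unique_pool) == nrow(poolSnps),
            nrow(comp$shared) + nrow(comp$unique_individual) ==
              nrow(indSnps))
  write.table(comp$shared, file.path(output_dir, "snp_shared.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  # mitogenome stage
  mito <- simulateMitogenome(defaultMitogenomeLayout(), seed = seed,
                             repeat_mutation = 0.02)
  truthProt <- mito$features[mito$features$kind == "protein", ]
  bnd <- mito$features$start[match("trnV", mito$features$name)]
  orfs <- scanOrfs(mito$genome, min_length = 300L, boundaries = bnd)
  for (r in seq_len(nrow(truthProt))) {
    hit <- orfs$start == truthProt$start[[r]] &
      orfs$end == truthProt$end[[r]] & orfs$strand == "+"
    stopifnot(any(hit))
  }
  reps <- findTandemRepeats(mito$genome, min_period = 20L,
                            max_period = 120L)
  writeFeatureTable(mito$features,
                    file.path(output_dir, "mitogenome_features.tsv"))

  # morphometrics stage
  ms <- cbind(cos(seq(0, 2 * pi, length.out = 13)[-13]),
              sin(seq(0, 2 * pi, length.out = 13)[-13]))
  off <- matrix(0, 12, 2); off2 <- off; off2[1, ] <- c(0.15, 0)
  shapes <- simulateLandmarks(ms, list(off, off2), noise_sd = 0.02,
                              sizes = c(12L, 12L), seed = seed)
  shapes <- gpa(shapes)
  an <- procrustesAnova(shapes, n_permutations = 999L, seed = seed)
  rw <- relativeWarps(shapes, alpha = 0)
  write.table(data.frame(id = shapes@ids, group = shapeGroups(shapes),
                         rw1 = rw$scores[, 1L], rw2 = rw$scores[, 2L]),
              file.path(output_dir, "rw_scores.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  # infection stage
  set.seed(seed)
  hostCounts <- rpois(9L, 17)
  inf <- infectionIndices(hostCounts)
  if (inf$infected > 0L)
    stopifnot(inf$raw$abundance <= inf$raw$mean_intensity + 1e-12)

  manifest <- list(package = "mitopool",
                   version = as.character(packageVersion("mitopool")),
                   seed = seed,
                   config = list(theta_per_site = theta_per_site,
                                 n_haplotypes = n_haplotypes,
                                 pool_size = pool_size,
                                 mean_depth = mean_depth),
                   outputs = list.files(output_dir))
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(popgen = stats, network = net, windows = wstats,
                 concordance = comp, mitogenome = mito, repeats = reps,
                 anova = an, infection = inf, manifest = manifest,
                 output_dir = output_dir))
}
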