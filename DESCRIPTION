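Package: mitopool
Title: Individual-Based and Pooled Mitochondrial Population Genetics for
    Monogenean Parasites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A comparative framework for contrasting individual-based
    (Sanger-style haplotype) and pooled next-generation-sequencing
    mitochondrial population genetics in monogenean flatworms. Provides
    readers and writers for FASTA, samtools text pileup, TPS landmark and
    feature-table formats; coalescent and two-stage pool-sequencing
    simulators; haplotype collapsing, diversity statistics, Tajima's D,
    FST/PhiST with permutation tests, and median-joining haplotype
    networks; pool-corrected windowed diversity estimation from pooled
    allele counts with minimum-count detection truncation; SNP concordance
    between individual and pooled call sets with false-positive frequency
    flags; circular mitogenome annotation arithmetic (alternative starts,
    abbreviated stop codons, GC content, tandem repeats, non-coding
    regions); landmark geometric morphometrics (generalized Procrustes
    analysis, semilandmark sliding by bending-energy minimisation,
    relative warps, permutation ANOVA, allometry); and standard
    parasitological infection descriptors.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    ape
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
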