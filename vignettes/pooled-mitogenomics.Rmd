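---
title: "Contrasting individual-based and pooled mitochondrial population genetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contrasting individual-based and pooled mitochondrial population genetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitopool)
```

## The scientific setting

Population-genetic surveys of small parasites face a practical dilemma.
The classical route sequences a mitochondrial marker (typically a *cox*1
fragment) individual by individual, yielding haplotypes from which
diversity, neutrality and differentiation statistics follow directly.
The pooled route extracts DNA from many individuals at once — often the
only way to obtain enough material from sub-millimetre monogenean
flatworms — and estimates allele frequencies from read counts over the
pool. The two routes sample the same population through very different
filters, and `mitopool` implements both ends plus the machinery needed
to compare them: simulators that generate data with the assumed
statistical structure, the individual-based estimators, the
pool-corrected estimators, a SNP concordance procedure, circular
mitogenome annotation arithmetic, and the landmark morphometrics used to
characterise the same worms phenotypically.

## Individual-based statistics

An alignment of `n` equal-length sequences yields:

* **Haplotype diversity** `h = n/(n-1) * (1 - sum(f_i^2))` over haplotype
  frequencies `f_i` (Nei's unbiased estimator).
* **Nucleotide diversity** `pi`: the mean pairwise proportion of
  differing sites. Sites where either member of a pair carries `N` or a
  gap are excluded from that pair's numerator and denominator; a pair
  with no comparable sites is an error, never a silent zero.
* **Tajima's D** `= (pi_total - S/a1) / sqrt(e1*S + e2*S*(S-1))` with
  the standard sample-size constants. `S = 0` raises a typed error: an
  undefined statistic is not zero.
* **Differentiation.** Two flavours are reported side by side because
  the classical literature is ambiguous about which one a given tool
  computes. `FST` is Nei's G_ST on haplotype frequencies with *plain*
  gene diversities — the plain form is the one for which two populations
  with identical haplotype composition give exactly 0 and two
  populations fixed for different haplotypes give exactly 1; any
  small-sample-corrected variant violates the first identity (it is
  negative whenever within-population diversity is high relative to the
  sample size). `PhiST` comes from one-level AMOVA variance components
  on pairwise difference counts. Both carry label-permutation p-values
  with explicit seeds.
* **Median-joining networks** are built in the Bandelt fashion:
  minimum-spanning networks are iterated over observed plus inferred
  median nodes, consensus-style quasi-medians of mutually connected
  triplets are proposed, candidates are accepted when they shorten the
  spanning length, and unused medians are pruned. Candidate medians are
  evaluated in lexicographic sequence order, so the construction is
  deterministic given its input. Positions at which all three triplet
  members disagree branch into all combinations; this branching is
  capped at 6 such positions per triplet (beyond which the first
  sequence's state is used), a bound that mitochondrial-scale data never
  approaches.

## The pooled estimators

Pooled sequencing observes a site through two binomial stages: `n`
individuals enter the pool, and `M` reads sample the pooled chromosomes.
A minimum allele count `b` guards against sequencing error, at the price
of truncating the site-frequency spectrum. Following the standard
pooled-sequencing correction logic, the package computes exact
expectation factors under the model: a site carries `k` derived copies
(`k = 1..n-1`, weighted proportionally `1/k` as under the neutral
spectrum), the derived read count is `m ~ Binomial(M, k/n)`, and the
site is detected iff `b <= m <= M - b`. Then

* `theta_pi = sum(site heterozygosity) / (w * pi_denominator)` where the
  per-site heterozygosity is the unbiased read-pair diversity
  `(M/(M-1))(1 - sum((c_a/M)^2))` and `pi_denominator` carries the
  pairwise weight `2m(M-m)/(M(M-1))`;
* `theta_W = S / (w * watterson_denominator)` with `S` the number of
  called SNPs in a window of `w` sites.

Both factors are computed by exact enumeration (binomial tail sums per
frequency class, memoized per distinct `(M, n, b)`), and validated in
the test suite against a million-site Monte-Carlo simulation of the same
model. Two limiting regimes are worth knowing: the pi factor approaches
1 as the pool grows (`(n-1)/n` without truncation), while the Watterson
factor approaches its classical value `a1(n)` only when depth dominates
the pool size — when `M` is comparable to `n`, singletons (frequency
`1/n`) are missed with probability near `exp(-M/n)` and the factor
correctly stays below `a1`.

Windows advance over the reference with configurable size and step
(defaults 300 bp / 10 bp; the *cox*1 fragment configuration uses a
392 bp window with a 2 bp step); the covered fraction counts sites
passing the coverage filters, masked positions (e.g. a tandem-repeat
region) count as uncovered, and windows below the minimum covered
fraction (default 0.6) have their statistics flagged undefined rather
than silently zeroed. The windowed Tajima's D is a *pool-adapted*
variant: the classical variance evaluated at an effective sample size
`min(n, floor(mean coverage))`. The exact variance adaptation used by
legacy pooled-sequencing tools is not published to the digit, so this
statistic is assessed by sign and calibration on simulations rather than
by digit-matching, and it always carries the sign of
`theta_pi - theta_W`.

## SNP concordance between the two routes

Call sets from the two routes are matched by position on the shared
fragment (a warning is raised when a shared position disagrees on the
minor allele — the matching rule itself stays positional). The
comparison reports shared and source-unique sites, the shared
percentages of each source (rounded half-up to the nearest integer, raw
ratios retained), and per pool-unique site two advisory flags:
`below_individual_floor` when its frequency is below `1/n_individual`
(strict inequality — a frequency exactly at the floor is attainable by
a real singleton) and `below_pool_singleton` when below `1/n_pool`.
Flags annotate; they never delete records, since sub-threshold sites are
a discussion item, not noise by definition. The detection floors
themselves are the singleton thresholds `1/n`: 0.0125 for a pool of 80
and 0.0147 for 68 sequenced individuals.

## Mitogenome annotation arithmetic

Coordinates are 1-based inclusive throughout, and a span wrapping the
circular origin is written `start-end` with `end < start`, so a span's
length is `end - start + 1` or `L - start + 1 + end`. Translation uses
NCBI table 9 (echinoderm/flatworm: `AGA`/`AGG` → Ser, `AAA` → Asn,
`TGA` → Trp), with abbreviated stop tails `T`/`TA` completed to `TAA`
by the polyadenylation convention. The ORF scanner reports, on both
strands and all frames across the origin, every allowed start
(`ATG`/`GTG`/`ATT` by default) paired with its first in-frame canonical
stop; abbreviated stops are only assigned against a caller-supplied
downstream boundary (e.g. a tRNA start), mirroring the division of
labour in mitogenome annotation where tRNA prediction is a separate
task. Tandem repeats are detected by a greedy period scan requiring at
least 80% identity between consecutive copies, with fractional final
copies and overlapping reports merged to the highest-copy array; this
follows the coarse conventions of the standard repeat finders without
reproducing their exact alignment scoring. Non-coding regions are the
maximal inter-feature gaps above a length threshold, reported with
their GC content.

## Landmark morphometrics

Generalized full Procrustes analysis centres each configuration, scales
to unit centroid size, and iterates least-squares rotation to the mean
(reflections disallowed) until the mean moves by less than `1e-10`.
Semilandmarks then slide along tangents estimated from their neighbours
in landmark order, minimising thin-plate-spline bending energy against
the reference; because each slide step solves the exact quadratic
minimisation over the tangent subspace (with the current position as a
feasible point), the bending energy is non-increasing step to step — a
property the test suite asserts on random datasets. Relative warps at
`alpha = 0` weight all partial warps equally and therefore coincide with
principal components of the aligned coordinates, which is also how the
implementation is verified; non-zero `alpha` reweights partial-warp
scores by the bending-energy eigenvalues to the power `-alpha/2`, with
the affine (uniform) component included unweighted behind a flag. Group
differences use Goodall's F with label permutation (default 10,000
iterations, seed exposed); allometry regresses shape on log centroid
size with size permutation. Axis orientations out of any of these
decompositions are arbitrary in sign, so comparisons are made up to
sign. Measurement tables are preprocessed in the order: exclude
specimens with more than 50% missing values (strict), impute remaining
gaps with per-variable observed means, then centre and scale to unit
variance; PCA of such a scaled matrix is equivalent to a
correlation-matrix PCA, which resolves the usual
covariance-vs-correlation ambiguity by construction.

## What the simulators emulate — and what they do not

`simulateHaplotypes` draws a Kingman coalescent genealogy and places
mutations under the infinite-sites model at rate `theta/2` per site per
unit branch length, so the expected nucleotide diversity equals
`theta_per_site`; the default 0.02 matches the high mitochondrial
diversity typical of these parasite populations, with 24 individually
sampled haplotypes and a pool of 80 at a few-hundred-fold coverage
(Poisson depth, mean 300 — Poisson rather than uniform, because the
coverage heterogeneity is precisely what the minimum-covered-fraction
filter exists to handle). Sequencing error is uniform, strand-agnostic
substitution at rate 0.001; indels are not simulated (the pileup
decoder's indel handling is exercised with hand-written lines instead).
A coalescent rather than forward simulator is the right null for a
non-recombining mitochondrial marker and makes the neutral expectations
(`E[pi] = theta`, `E[D]` near 0) exact test oracles. The mitogenome
generator realizes a declared layout — genes with chosen start/stop
codons and no internal in-frame stops, AT-rich non-coding regions with
target GC, a repeat region with optional per-copy mutation — so
annotation operations can be tested for exact truth recovery. The
landmark generator adds group offsets, allometric shape change linear in
centred log size, and isotropic noise before hiding everything behind a
random similarity transform.

None of this reproduces read-level artefacts (quality models, adapters,
reference bias, PCR duplicates), selection, demography beyond the
neutral coalescent, or digitisation error structure in landmarks.
Passing tests therefore certify the estimators and their sampling
corrections under the stated models — not the upstream wet-lab and
mapping pipeline, which is out of scope by design.

## Numerical choices and problem sizes

Permutation p-values use the `(1 + hits)/(1 + n)` convention and never
exceed 1. Undefined statistics raise typed errors (or are flagged `NA`
in windowed output), never silent zeros. MJ tie-breaks are
lexicographic; SNP major/minor ties resolve alphabetically. The test
suite sizes its simulations to desk scale: oracle equivalences on 100+
random instances, pool parameter recovery over 200 replicated pools of
80 haplotypes at depth 300 over 1.5 kb (mean `theta_pi` within 15% of
truth), correction factors against 10^6 Monte-Carlo sites within 3
standard errors, permutation type-I calibration over 200 seeds
(rejection rate in [0.02, 0.09] at nominal 0.05), and 5,000 coalescent
replicates for the neutrality-test null (mean D in [-0.3, 0.1],
reflecting the statistic's slight negative skew at moderate `theta`).
These sizes were chosen as the smallest at which the binomial/Monte
Carlo tolerances above are comfortably discriminating.

## Known limitations

* The pooled Tajima's D variance is an explicit approximation (see
  above); compare pools analysed with identical settings only.
* The repeat detector reports arrays, not alignments; period estimates
  near array boundaries can shift by a few bases when flanking sequence
  partially matches the motif.
* `FST` and `PhiST` are two-population; hierarchical AMOVA is not
  implemented.
* TPS parsing covers the `LM=`/`ID=`/`IMAGE=`/`SCALE=` dialect only,
  and landmark roles (fixed vs semi) must be supplied by the caller —
  the format does not encode them.

## A worked run

```{r demo, eval = FALSE}
out <- runDemo(seed = 1, output_dir = "demo_out")
out$popgen            # haplotype/nucleotide diversity, Tajima's D
out$concordance       # shared vs unique SNPs with threshold flags
out$infection         # prevalence / intensity / abundance
```

The demo chains every module on one seed, asserts the cross-module
invariants (partition identities, non-negative diversities, exact
annotation recovery) and writes plain-text tables plus a JSON manifest;
a second run with the same seed reproduces the tables byte for byte.
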