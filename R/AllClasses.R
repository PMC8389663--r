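#' @import methods
#' @importFrom stats rbinom rpois rmultinom rexp runif rnorm rlnorm
#'   dbinom pbinom sd cor prcomp var
#' @importFrom utils head tail write.table read.table packageVersion
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Aligned haplotype sample with population labels
#'
#' The substrate of individual-based mitochondrial statistics: a set of
#' equal-length aligned nucleotide sequences (one per sequenced individual)
#' plus an optional population label per sequence.
#'
#' @slot sequences Named character vector; names are unique non-empty
#'   identifiers, values are uppercase strings over `A,C,G,T,N,-`, all of
#'   the same length.
#' @slot populations Named character vector of population labels, parallel
#'   to `sequences` (may be empty).
#'
#' @exportClass HapAlignment
setClass("HapAlignment",
  representation(sequences = "character", populations = "character"))

setValidity("HapAlignment", function(object) {
  s <- object@sequences
  if (length(s) < 1L) return("alignment must contain at least one sequence")
  ids <- names(s)
  if (is.null(ids) || any(!nzchar(ids))) return("sequence ids must be non-empty")
  if (anyDuplicated(ids)) return(paste0("duplicate sequence id: ",
    ids[duplicated(ids)][1L]))
  if (length(unique(nchar(s))) != 1L) return("sequences must have equal length")
  if (nchar(s[[1L]]) < 1L) return("alignment length must be >= 1")
  if (any(grepl("[^ACGTN-]", s))) return("residues must be over A,C,G,T,N,-")
  p <- object@populations
  if (length(p) && !all(names(p) %in% ids))
    return("population labels refer to unknown sequence ids")
  TRUE
})

#' Construct a HapAlignment
#'
#' @param sequences Named character vector of aligned sequences (names are
#'   ids). Residues are uppercased on construction.
#' @param populations Optional named character vector mapping sequence ids
#'   to population labels.
#' @return A [HapAlignment-class] object.
#' @examples
#' aln <- HapAlignment(c(a = "ACGT", b = "ACGA"))
#' alnLength(aln)
#' @export
HapAlignment <- function(sequences, populations = character()) {
  seqs <- toupper(as.character(sequences))
  names(seqs) <- names(sequences)
  pops <- as.character(populations)
  names(pops) <- names(populations)
  new("HapAlignment", sequences = seqs, populations = pops)
}

#' @describeIn HapAlignment Number of sequences in the alignment.
#' @param x,object A `HapAlignment`.
#' @export
sampleSize <- function(x) length(x@sequences)

#' @describeIn HapAlignment Alignment length in sites.
#' @export
alnLength <- function(x) nchar(x@sequences[[1L]])

#' @describeIn HapAlignment Named character vector of aligned sequences.
#' @export
alnSequences <- function(x) x@sequences

#' @describeIn HapAlignment Named character vector of population labels.
#' @export
alnPopulations <- function(x) x@populations

setMethod("show", "HapAlignment", function(object) {
  cat("HapAlignment:", sampleSize(object), "sequences x",
      alnLength(object), "sites\n")
  if (length(object@populations))
    cat("  populations:",
        paste(names(table(object@populations)), collapse = ", "), "\n")
})

#' Collapsed haplotype table
#'
#' Distinct sequences of an alignment with their multiplicities and member
#' ids, plus the count of polymorphic sites.
#'
#' @slot haplotypes Character vector of distinct sequences.
#' @slot counts Integer multiplicities (sum to the sample size).
#' @slot members List of character vectors of member ids per haplotype.
#' @slot nPolymorphic Integer count of polymorphic sites (>= 2 observed
#'   non-N states; gaps count as a fifth state).
#'
#' @exportClass HaplotypeTable
setClass("HaplotypeTable",
  representation(haplotypes = "character", counts = "integer",
                 members = "list", nPolymorphic = "integer"))

setValidity("HaplotypeTable", function(object) {
  if (anyDuplicated(object@haplotypes)) return("haplotypes must be distinct")
  if (length(object@haplotypes) != length(object@counts))
    return("counts length mismatch")
  if (any(object@counts < 1L)) return("counts must be positive")
  if (length(object@members) != length(object@haplotypes))
    return("members length mismatch")
  if (sum(lengths(object@members)) != sum(object@counts))
    return("member lists inconsistent with counts")
  TRUE
})

setMethod("show", "HaplotypeTable", function(object) {
  cat("HaplotypeTable:", length(object@haplotypes), "haplotypes from",
      sum(object@counts), "sequences;", object@nPolymorphic,
      "polymorphic sites\n")
})

#' @describeIn HaplotypeTable Haplotype multiplicities.
#' @param x,object A `HaplotypeTable`.
#' @export
hapCounts <- function(x) x@counts

#' @describeIn HaplotypeTable Distinct haplotype sequences.
#' @export
hapSequences <- function(x) x@haplotypes

#' @describeIn HaplotypeTable Number of polymorphic sites.
#' @export
nPolymorphicSites <- function(x) x@nPolymorphic

#' Median-joining haplotype network
#'
#' Observed haplotypes plus inferred median (Steiner) node sequences, with
#' mutation-count edge weights.
#'
#' @slot nodes Data frame with columns `id`, `sequence`, `kind`
#'   (`"observed"` or `"median"`), `count`.
#' @slot edges Data frame with columns `from`, `to`, `weight`.
#'
#' @exportClass MJNetwork
setClass("MJNetwork", representation(nodes = "data.frame", edges = "data.frame"))

setValidity("MJNetwork", function(object) {
  n <- object@nodes
  if (!all(c("id", "sequence", "kind") %in% names(n)))
    return("nodes must have id/sequence/kind")
  if (anyDuplicated(n$id)) return("node ids must be unique")
  if (!all(n$kind %in% c("observed", "median"))) return("bad node kind")
  e <- object@edges
  if (nrow(e) && !all(c(e$from, e$to) %in% n$id))
    return("edge endpoints must be nodes")
  TRUE
})

setMethod("show", "MJNetwork", function(object) {
  cat("MJNetwork:", sum(object@nodes$kind == "observed"), "observed +",
      sum(object@nodes$kind == "median"), "median nodes,",
      nrow(object@edges), "edges (total length",
      sum(object@edges$weight), ")\n")
})

#' @describeIn MJNetwork Node table.
#' @param x,object An `MJNetwork`.
#' @export
networkNodes <- function(x) x@nodes

#' @describeIn MJNetwork Edge table.
#' @export
networkEdges <- function(x) x@edges

#' Circular (or linear) mitochondrial genome sequence
#'
#' @slot residues Uppercase nucleotide string.
#' @slot circular Logical; `TRUE` for a circular molecule, in which case
#'   coordinate spans may wrap the origin (written `start-end` with
#'   `end < start`).
#'
#' @exportClass CircularGenome
setClass("CircularGenome",
  representation(residues = "character", circular = "logical"))

setValidity("CircularGenome", function(object) {
  if (length(object@residues) != 1L || nchar(object@residues) < 1L)
    return("residues must be a single non-empty string")
  if (grepl("[^ACGTN]", object@residues)) return("residues must be A,C,G,T,N")
  TRUE
})

#' Construct a CircularGenome
#'
#' @param residues Nucleotide string (uppercased on construction).
#' @param circular Logical, default `TRUE`.
#' @return A [CircularGenome-class].
#' @examples
#' g <- CircularGenome("ACGTACGT")
#' genomeLength(g)
#' @export
CircularGenome <- function(residues, circular = TRUE) {
  new("CircularGenome", residues = toupper(residues), circular = circular)
}

#' @describeIn CircularGenome Genome length in bp.
#' @param x,object A `CircularGenome`.
#' @export
genomeLength <- function(x) nchar(x@residues)

#' @describeIn CircularGenome The full nucleotide string.
#' @export
genomeSequence <- function(x) x@residues

#' @describeIn CircularGenome Is the molecule circular?
#' @export
isCircular <- function(x) x@circular

setMethod("show", "CircularGenome", function(object) {
  cat(if (object@circular) "Circular" else "Linear", "genome of",
      genomeLength(object), "bp\n")
})

#' Landmark shape dataset
#'
#' A set of 2-D landmark configurations with identical landmark count and
#' roles, optionally Procrustes-superimposed.
#'
#' @slot coords Numeric array `k x 2 x n` of raw coordinates.
#' @slot aligned Numeric array `k x 2 x n` of superimposed coordinates, or
#'   a 0-extent array before alignment.
#' @slot roles Character vector length `k`, entries `"fixed"` or `"semi"`.
#' @slot ids Character specimen identifiers (length `n`).
#' @slot groups Character group labels (length `n`, may be empty).
#' @slot centroidSizes Numeric centroid sizes (filled by [gpa()]).
#'
#' @exportClass ShapeDataset
setClass("ShapeDataset",
  representation(coords = "array", aligned = "array", roles = "character",
                 ids = "character", groups = "character",
                 centroidSizes = "numeric"))

setValidity("ShapeDataset", function(object) {
  d <- dim(object@coords)
  if (length(d) != 3L || d[2L] != 2L) return("coords must be k x 2 x n")
  if (d[1L] < 3L) return("at least 3 landmarks required")
  if (length(object@roles) != d[1L]) return("roles length must equal k")
  if (!all(object@roles %in% c("fixed", "semi"))) return("roles: fixed|semi")
  if (length(object@ids) != d[3L]) return("ids length must equal n")
  if (length(object@groups) && length(object@groups) != d[3L])
    return("groups length must equal n")
  TRUE
})

#' Construct a ShapeDataset
#'
#' @param coords `k x 2 x n` array, or a list of `k x 2` matrices.
#' @param roles Character vector (`"fixed"`/`"semi"`) of length `k`;
#'   defaults to all fixed.
#' @param ids Specimen identifiers; default `s1..sn`.
#' @param groups Optional group labels per specimen.
#' @return A [ShapeDataset-class].
#' @export
ShapeDataset <- function(coords, roles = NULL, ids = NULL, groups = character()) {
  if (is.list(coords))
    coords <- array(unlist(coords), dim = c(nrow(coords[[1L]]), 2L, length(coords)))
  k <- dim(coords)[1L]; n <- dim(coords)[3L]
  if (is.null(roles)) roles <- rep("fixed", k)
  if (is.null(ids)) ids <- paste0("s", seq_len(n))
  new("ShapeDataset", coords = coords,
      aligned = array(numeric(0), dim = c(0L, 0L, 0L)),
      roles = roles, ids = as.character(ids),
      groups = as.character(groups), centroidSizes = numeric(0))
}

#' @describeIn ShapeDataset Number of specimens.
#' @param x,object A `ShapeDataset`.
#' @export
nSpecimens <- function(x) dim(x@coords)[3L]

#' @describeIn ShapeDataset Number of landmarks.
#' @export
nLandmarks <- function(x) dim(x@coords)[1L]

#' @describeIn ShapeDataset Superimposed coordinate array (errors if the
#'   dataset has not been through [gpa()]).
#' @export
alignedCoords <- function(x) {
  if (length(x@aligned) == 0L)
    stop("dataset has not been superimposed; run gpa() first")
  x@aligned
}

#' @describeIn ShapeDataset Centroid sizes of the raw configurations.
#' @export
centroidSizes <- function(x) x@centroidSizes

#' @describeIn ShapeDataset Group labels.
#' @export
shapeGroups <- function(x) x@groups

setMethod("show", "ShapeDataset", function(object) {
  cat("ShapeDataset:", nSpecimens(object), "specimens x",
      nLandmarks(object), "landmarks (",
      sum(object@roles == "semi"), "semi )",
      if (length(object@aligned)) "[superimposed]" else "[raw]", "\n")
})
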