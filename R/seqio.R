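#' Read a FASTA file
#'
#' Records start at lines beginning `>`; residues are concatenated across
#' wrapped lines and uppercased. Identifiers (the header up to the first
#' whitespace) must be unique and non-empty.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences (names are record ids).
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">a", "AC", "GT"), f)
#' readFasta(f)
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("FASTA format error in ", path,
                                           ": ", conditionMessage(e)))
  if (length(set) == 0L) stop("FASTA format error: empty file ", path)
  ids <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(ids))) stop("FASTA format error: empty record id")
  if (anyDuplicated(ids))
    stop("FASTA format error: duplicate id '", ids[duplicated(ids)][1L], "'")
  stats::setNames(toupper(as.character(set)), ids)
}

#' Write sequences to FASTA
#'
#' @param sequences Named character vector (as returned by [readFasta()]).
#' @param path Output path.
#' @param width Line-wrap width (default 70).
#' @return Invisibly, `path`.
#' @export
writeFasta <- function(sequences, path, width = 70L) {
  ids <- names(sequences)
  if (is.null(ids) || any(!nzchar(ids))) stop("sequences must be named")
  con <- file(path, "w"); on.exit(close(con))
  for (i in seq_along(sequences)) {
    writeLines(paste0(">", ids[[i]]), con)
    s <- sequences[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

# Decode one pileup read-base string into A/C/G/T counts.
# Grammar handled: "."/"," reference match; ACGT (any case) mismatch;
# "^X" read start (X = mapping quality, skipped); "$" read end;
# "+n<seq>"/"-n<seq>" indels (skipped); "*" deletion placeholder and "N"
# excluded from counts but counted against declared depth.
decodePileupBases <- function(bases, ref, line = NA_integer_) {
  counts <- c(A = 0L, C = 0L, G = 0L, T = 0L)
  excluded <- 0L
  chars <- strsplit(bases, "", fixed = TRUE)[[1L]]
  i <- 1L; n <- length(chars)
  while (i <= n) {
    ch <- chars[[i]]
    if (ch == "^") {
      i <- i + 2L                       # caret consumes the mapping-quality char
    } else if (ch == "$") {
      i <- i + 1L
    } else if (ch == "+" || ch == "-") {
      j <- i + 1L
      while (j <= n && chars[[j]] %in% as.character(0:9)) j <- j + 1L
      if (j == i + 1L)
        stop("pileup format error: malformed indel length at line ", line)
      len <- as.integer(paste(chars[(i + 1L):(j - 1L)], collapse = ""))
      if (j + len - 1L > n)
        stop("pileup format error: indel overruns field at line ", line)
      i <- j + len
    } else {
      up <- toupper(ch)
      if (ch == "." || ch == ",") {
        if (ref %in% DNA_BASES) counts[[ref]] <- counts[[ref]] + 1L
        else excluded <- excluded + 1L
      } else if (up %in% DNA_BASES) {
        counts[[up]] <- counts[[up]] + 1L
      } else {
        excluded <- excluded + 1L       # "*", "N", other ambiguity codes
      }
      i <- i + 1L
    }
  }
  list(counts = counts, excluded = excluded)
}

#' Read a samtools text pileup file
#'
#' Expects the 6-column samtools text pileup (chrom, 1-based position,
#' reference base, depth, read bases, base qualities); extra columns are
#' ignored. The read-base column is decoded per the pileup grammar:
#' `.`/`,` count as the reference base, `A/C/G/T` (any case) as
#' themselves, `^X` start markers and `$` end markers are skipped,
#' `+n.../-n...` indel fields are skipped, and `*`/`N` are excluded from
#' counts. A declared depth that disagrees with the decoded base count by
#' more than the excluded symbols triggers a warning (decoded counts are
#' kept).
#'
#' @param path Path to a pileup text file.
#' @return Data frame with columns `chrom`, `pos`, `ref`, `depth` (declared),
#'   `A`, `C`, `G`, `T`. Positions are strictly increasing within a
#'   chromosome.
#' @export
readPileup <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L)
    return(data.frame(chrom = character(), pos = integer(), ref = character(),
                      depth = integer(), A = integer(), C = integer(),
                      G = integer(), T = integer()))
  fields <- strsplit(lines, "[ \t]+")
  out <- vector("list", length(lines))
  for (ln in seq_along(fields)) {
    f <- fields[[ln]]
    if (length(f) < 5L)
      stop("pileup format error: fewer than 5 columns at line ", ln)
    depth <- suppressWarnings(as.integer(f[[4L]]))
    if (is.na(depth))
      stop("pileup format error: non-integer depth at line ", ln)
    bases <- if (depth == 0L && length(f) < 6L) "" else f[[5L]]
    dec <- decodePileupBases(bases, toupper(f[[3L]]), ln)
    if (sum(dec$counts) + dec$excluded != depth)
      warning("pileup depth mismatch at line ", ln, ": declared ", depth,
              ", decoded ", sum(dec$counts), " + ", dec$excluded, " excluded")
    out[[ln]] <- data.frame(chrom = f[[1L]], pos = as.integer(f[[2L]]),
                            ref = toupper(f[[3L]]), depth = depth,
                            A = dec$counts[["A"]], C = dec$counts[["C"]],
                            G = dec$counts[["G"]], T = dec$counts[["T"]])
  }
  res <- do.call(rbind, out)
  for (chr in unique(res$chrom)) {
    p <- res$pos[res$chrom == chr]
    if (any(diff(p) <= 0L))
      stop("pileup format error: positions not strictly increasing on ", chr)
  }
  rownames(res) <- NULL
  res
}

#' Write site counts as a samtools-style text pileup
#'
#' Inverse of [readPileup()] on its output dialect: reference-matching
#' reads are written as `.`, mismatches as their base, and qualities as
#' `I`.
#'
#' @param sites Data frame with columns `chrom`, `pos`, `ref`, `A`, `C`,
#'   `G`, `T` (a `depth` column, if present, is ignored in favour of the
#'   decoded total).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writePileup <- function(sites, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (i in seq_len(nrow(sites))) {
    ref <- sites$ref[[i]]
    parts <- character(0)
    for (b in DNA_BASES) {
      cnt <- sites[[b]][[i]]
      if (cnt > 0L)
        parts <- c(parts, strrep(if (b == ref) "." else b, cnt))
    }
    bases <- paste(parts, collapse = "")
    depth <- sum(sites$A[[i]], sites$C[[i]], sites$G[[i]], sites$T[[i]])
    writeLines(paste(sites$chrom[[i]], sites$pos[[i]], ref, depth,
                     if (depth > 0L) bases else "*",
                     if (depth > 0L) strrep("I", depth) else "*",
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Read a TPS landmark file
#'
#' Parses the `tpsDig` dialect: records are delimited by `LM=k` headers
#' followed by `k` whitespace-separated coordinate pairs, with optional
#' `ID=`, `IMAGE=` and `SCALE=` lines. A missing `SCALE` defaults to 1.
#' Roles (fixed vs sliding semilandmarks) are assigned by the caller via
#' `semiIndices`, since the TPS format does not carry them.
#'
#' @param path Path to a TPS file.
#' @param physical If `TRUE`, coordinates are multiplied by the record's
#'   scale factor (physical units); default stores digitiser units.
#' @return List of landmark configurations, each a list with `id`,
#'   `points` (`k x 2` matrix), `scale`.
#' @export
readTps <- function(path, physical = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  configs <- list(); i <- 1L; n <- length(lines); rec <- 0L
  while (i <= n) {
    if (!grepl("^LM\\s*=", lines[[i]], ignore.case = TRUE))
      stop("TPS format error: expected LM= header at line ", i)
    k <- suppressWarnings(as.integer(sub("^LM\\s*=\\s*", "", lines[[i]],
                                         ignore.case = TRUE)))
    if (is.na(k) || k < 1L) stop("TPS format error: bad LM count at line ", i)
    i <- i + 1L; rec <- rec + 1L
    pts <- matrix(NA_real_, k, 2L); got <- 0L
    while (i <= n && got < k && !grepl("^(LM|ID|IMAGE|SCALE)\\s*=",
                                       lines[[i]], ignore.case = TRUE)) {
      xy <- suppressWarnings(as.numeric(strsplit(lines[[i]], "\\s+")[[1L]]))
      if (length(xy) != 2L || anyNA(xy))
        stop("TPS format error: non-numeric coordinate at line ", i)
      got <- got + 1L; pts[got, ] <- xy; i <- i + 1L
    }
    if (got != k)
      stop("TPS format error: record ", rec, " has ", got,
           " coordinates, expected ", k)
    id <- paste0("specimen", rec); scale <- 1
    while (i <= n && grepl("^(ID|IMAGE|SCALE)\\s*=", lines[[i]],
                           ignore.case = TRUE)) {
      key <- toupper(sub("\\s*=.*$", "", lines[[i]]))
      val <- sub("^[^=]*=\\s*", "", lines[[i]])
      if (key == "ID") id <- val
      if (key == "SCALE") {
        scale <- suppressWarnings(as.numeric(val))
        if (is.na(scale) || scale <= 0)
          stop("TPS format error: bad SCALE at line ", i)
      }
      i <- i + 1L
    }
    if (physical) pts <- pts * scale
    configs[[rec]] <- list(id = id, points = pts, scale = scale)
  }
  if (rec == 0L) stop("TPS format error: empty file ", path)
  configs
}

#' Write landmark configurations in TPS format
#'
#' @param configs List of configurations as returned by [readTps()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeTps <- function(configs, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (cfg in configs) {
    writeLines(paste0("LM=", nrow(cfg$points)), con)
    writeLines(paste(format(cfg$points[, 1L], trim = TRUE, digits = 15),
                     format(cfg$points[, 2L], trim = TRUE, digits = 15)), con)
    writeLines(paste0("ID=", cfg$id), con)
    writeLines(paste0("SCALE=", format(cfg$scale, digits = 15)), con)
  }
  invisible(path)
}

#' Write an annotation feature table
#'
#' Tab-delimited table in the conventional mitogenome-annotation layout:
#' columns `Region`, `Position`, `Length`, `Start.Stop.Codon`, `Anticodon`.
#' Positions are 1-based inclusive; a span wrapping the circular origin is
#' written `start-end` with `end < start`.
#'
#' @param features Data frame with columns `name`, `start`, `end`,
#'   `length`, and optionally `start_codon`, `stop_codon`, `anticodon`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeFeatureTable <- function(features, path) {
  if (nrow(features) && anyDuplicated(features$name))
    stop("duplicate feature name: ",
         features$name[duplicated(features$name)][1L])
  codon <- if (nrow(features) == 0L || is.null(features$start_codon))
    character(nrow(features))
  else ifelse(!is.na(features$start_codon) & nzchar(features$start_codon),
              paste0(features$start_codon, "/", features$stop_codon), "")
  anti <- if ("anticodon" %in% names(features)) features$anticodon
          else rep("", nrow(features))
  anti[is.na(anti)] <- ""
  out <- data.frame(Region = features$name,
                    Position = if (nrow(features))
                      paste0(features$start, "-", features$end) else character(0),
                    Length = features$length,
                    Start.Stop.Codon = codon,
                    Anticodon = anti)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Missing start_codon columns tolerated
utils::globalVariables(character(0))
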