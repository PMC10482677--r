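#' @importFrom Biostrings matchPattern neditStartingAt
NULL

#' Map one junction read to the reference
#'
#' Scans both strands of every chromosome for placements of the read within
#' Hamming distance `maxMismatches` (substitutions only, no indels; `N`
#' never matches a reference base). The unique best placement is reported;
#' two or more placements tying at the minimal distance make the read
#' ambiguous, and it is discarded rather than assigned at random. A read
#' longer than every chromosome is unmapped, not an error.
#'
#' The reported `position` is the 1-based coordinate of the read's first
#' reference base on the forward strand; `orientation` is the strand
#' matched, i.e. the strand of the gene-trap cassette.
#'
#' @param read a character string or `DNAString` over A/C/G/T/N.
#' @param genome a [ToyGenome-class] (or any object with a `DNAStringSet`
#'   in its `sequences` slot).
#' @param maxMismatches maximum Hamming distance tolerated (default 1).
#' @return A list with elements `status` (`"unique"`, `"ambiguous"` or
#'   `"unmapped"`), and for unique placements `chromosome`, `position`,
#'   `orientation` and `mismatches`.
#' @examples
#' genome <- buildToyGenome(sortedScreenConfig(seed = 1L))
#' rd <- substr(as.character(genomeSequences(genome)[[1]]), 101, 150)
#' mapRead(rd, genome)
#' @export
mapRead <- function(read, genome, maxMismatches = 1L) {
  chars <- strsplit(toupper(as.character(read)), "")[[1L]]
  if (!length(chars)) stop("read must be non-empty")
  if (!all(chars %in% c("A", "C", "G", "T", "N")))
    stop("read alphabet must be A/C/G/T/N")
  pat <- if (is(read, "DNAString")) read
         else DNAString(paste(chars, collapse = ""))
  hits <- .scanPlacements(pat, genome@sequences, maxMismatches)
  if (nrow(hits) == 0L) return(list(status = "unmapped"))
  best <- min(hits$mismatches)
  hits <- hits[hits$mismatches == best, , drop = FALSE]
  if (nrow(hits) > 1L) return(list(status = "ambiguous"))
  list(status = "unique",
       chromosome = hits$chromosome,
       position = hits$position,
       orientation = hits$orientation,
       mismatches = hits$mismatches)
}

# all placements of pat within maxMismatches, both strands, all chromosomes
.scanPlacements <- function(pat, sequences, maxMismatches) {
  out <- list()
  rcp <- reverseComplement(pat)
  for (chrom in names(sequences)) {
    subject <- sequences[[chrom]]
    if (length(pat) > length(subject)) next
    for (ori in c("+", "-")) {
      p <- if (ori == "+") pat else rcp
      m <- matchPattern(p, subject, max.mismatch = maxMismatches,
                        with.indels = FALSE, fixed = TRUE)
      if (length(m) == 0L) next
      nmm <- neditStartingAt(p, subject, starting.at = start(m),
                             with.indels = FALSE, fixed = TRUE)
      out[[length(out) + 1L]] <- data.frame(
        chromosome = chrom, position = start(m), orientation = ori,
        mismatches = as.integer(nmm), stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(chromosome = character(), position = integer(),
                      orientation = character(), mismatches = integer()))
  do.call(rbind, out)
}

#' Map a set of junction reads
#'
#' Applies [mapRead()] to every read and reports the outcome per read plus
#' summary counts (total, uniquely mapped, ambiguous, unmapped), the TSV
#' mapping report of a screen run.
#'
#' @param reads a named `DNAStringSet` (or character vector) of reads.
#' @param genome a [ToyGenome-class].
#' @param maxMismatches maximum Hamming distance tolerated (default 1).
#' @return A `DataFrame` with one row per read (`read`, `status`,
#'   `chromosome`, `position`, `orientation`, `mismatches`); the summary
#'   counts are stored in `metadata(.)$report`.
#' @export
mapReads <- function(reads, genome, maxMismatches = 1L) {
  reads <- DNAStringSet(reads)
  res <- lapply(seq_along(reads), function(i)
    mapRead(reads[[i]], genome, maxMismatches))
  status <- vapply(res, `[[`, "", "status")
  uniq <- status == "unique"
  out <- DataFrame(
    read = if (is.null(names(reads))) as.character(seq_along(reads))
           else names(reads),
    status = status,
    chromosome = NA_character_, position = NA_integer_,
    orientation = NA_character_, mismatches = NA_integer_)
  if (any(uniq)) {
    out$chromosome[uniq] <- vapply(res[uniq], `[[`, "", "chromosome")
    out$position[uniq] <- vapply(res[uniq], function(x)
      as.integer(x$position), 0L)
    out$orientation[uniq] <- vapply(res[uniq], `[[`, "", "orientation")
    out$mismatches[uniq] <- vapply(res[uniq], function(x)
      as.integer(x$mismatches), 0L)
  }
  metadata(out)$report <- data.frame(
    n_reads = length(reads),
    n_unique = sum(uniq),
    n_ambiguous = sum(status == "ambiguous"),
    n_unmapped = sum(status == "unmapped"))
  out
}

#' Collapse unique read mappings into insertion sites
#'
#' Groups mappings by (chromosome, position, orientation); each group
#' becomes one insertion site whose `support` is the group size (reads are
#' evidence, unique sites are what is counted). Output is sorted by
#' coordinate. The operation is idempotent — collapsing an already
#' collapsed set sums supports and changes nothing else — and independent
#' of input order.
#'
#' @param mappings either the `DataFrame` returned by [mapReads()] (rows
#'   with `status != "unique"` are dropped) or a width-1 `GRanges` of
#'   sites, optionally with a `support` mcol.
#' @param population population label (`"high"` or `"low"`) stamped on
#'   every site.
#' @return A sorted width-1 `GRanges` with mcols `population` and
#'   `support`.
#' @export
collapseSites <- function(mappings, population) {
  if (is(mappings, "GRanges")) {
    chrom <- as.character(seqnames(mappings))
    pos <- start(mappings)
    ori <- as.character(strand(mappings))
    sup <- if (is.null(mappings$support)) rep(1L, length(mappings))
           else mappings$support
  } else {
    keep <- mappings$status == "unique"
    chrom <- mappings$chromosome[keep]
    pos <- mappings$position[keep]
    ori <- mappings$orientation[keep]
    sup <- rep(1L, sum(keep))
  }
  if (!length(chrom)) {
    gr <- GRanges()
    gr$population <- character()
    gr$support <- integer()
    return(gr)
  }
  key <- paste(chrom, pos, ori)
  supTot <- tapply(sup, key, sum)
  first <- !duplicated(key)
  gr <- GRanges(chrom[first], IRanges(pos[first], width = 1L),
                strand = ori[first])
  gr$population <- population
  gr$support <- as.integer(supTot[key[first]])
  .sortSites(gr)
}
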