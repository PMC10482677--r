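suppressPackageStartupMessages({
  library(S4Vectors)
  library(GenomicRanges)
  library(Biostrings)
})

# Brute-force two-sided Fisher oracle: linear-space enumeration over the
# full hypergeometric support using choose(), independent of the
# log-space implementation. Valid for H + L <= ~200.
fisherOracle <- function(a, H, b, L) {
  k <- a + b
  xs <- max(0, k - L):min(H, k)
  p <- choose(H, xs) * choose(L, k - xs) / choose(H + L, k)
  obs <- choose(H, a) * choose(L, k - a) / choose(H + L, k)
  sum(p[p <= obs * (1 + 1e-7)])
}

# Naive all-positions Hamming scan over both strands of every chromosome;
# returns every placement within maxMismatches as a data.frame.
naiveScan <- function(read, sequences, maxMismatches = 1L) {
  readc <- strsplit(toupper(as.character(read)), "")[[1L]]
  L <- length(readc)
  comp <- function(x) rev(chartr("ACGTN", "TGCAN", x))
  out <- list()
  for (chrom in names(sequences)) {
    refc <- strsplit(as.character(sequences[[chrom]]), "")[[1L]]
    n <- length(refc)
    if (L > n) next
    for (ori in c("+", "-")) {
      rd <- if (ori == "+") readc else comp(readc)
      starts <- seq_len(n - L + 1L)
      mm <- integer(length(starts))
      for (off in seq_len(L))
        mm <- mm + (refc[starts + off - 1L] != rd[off])
      hit <- which(mm <= maxMismatches)
      if (length(hit))
        out[[length(out) + 1L]] <- data.frame(
          chromosome = chrom, position = starts[hit], orientation = ori,
          mismatches = mm[hit], stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(chromosome = character(), position = integer(),
                      orientation = character(), mismatches = integer()))
  do.call(rbind, out)
}

# mapRead outcome predicted by the naive scan
naiveMap <- function(read, sequences, maxMismatches = 1L) {
  hits <- naiveScan(read, sequences, maxMismatches)
  if (nrow(hits) == 0L) return(list(status = "unmapped"))
  best <- hits[hits$mismatches == min(hits$mismatches), , drop = FALSE]
  if (nrow(best) > 1L) return(list(status = "ambiguous"))
  list(status = "unique", chromosome = best$chromosome,
       position = best$position, orientation = best$orientation,
       mismatches = best$mismatches)
}

# A deterministic 100 bp toy genome with one fully specified + strand gene
# (body 21-60) and one - strand gene (body 71-90), built by hand so every
# region boundary is known exactly.
makeTinyGenome <- function() {
  seq <- DNAStringSet(paste(rep(c("A", "C", "G", "T"), 25), collapse = ""))
  names(seq) <- "chr1"
  genes <- GRanges("chr1", IRanges(c(21L, 71L), c(60L, 90L)),
                   strand = c("+", "-"),
                   gene_id = c("geneA", "geneB"))
  regions <- GRanges("chr1",
    IRanges(c(21L, 29L, 45L, 53L,   71L, 77L, 83L),
            c(28L, 44L, 52L, 60L,   76L, 82L, 90L)),
    strand = c(rep("+", 4), rep("-", 3)),
    gene_id = c(rep("geneA", 4), rep("geneB", 3)),
    kind = c("five_prime_utr", "exon", "intron", "three_prime_utr",
             "three_prime_utr", "exon", "five_prime_utr"))
  new("ToyGenome", sequences = seq, genes = genes, regions = regions)
}

# Width-1 site GRanges shorthand
makeSites <- function(pos, strand, population = "high",
                      chrom = "chr1") {
  gr <- GRanges(chrom, IRanges(pos, width = 1L), strand = strand)
  gr$population <- population
  gr
}

# Small screen configuration used across tests (fast, but deep enough for
# per-gene counts in the double digits)
smallConfig <- function(seed, ...) {
  sortedScreenConfig(nCells = 20000L, cellsSortedPerTail = 800L,
                     seed = seed, ...)
}
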