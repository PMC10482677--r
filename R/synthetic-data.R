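#' @importFrom Biostrings DNAString DNAStringSet reverseComplement
#'   writeXStringSet readDNAStringSet
#' @importFrom IRanges Views
#' @importFrom GenomicRanges reduce gaps findOverlaps
#' @importFrom S4Vectors queryHits subjectHits
#' @importFrom stats rnorm rmultinom runif
#' @importFrom withr with_seed
NULL

# random composition of n into k parts, each >= 1
.randomComposition <- function(n, k) {
  if (k == 1L) return(n)
  cuts <- sort(sample.int(n - 1L, k - 1L))
  diff(c(0L, cuts, n))
}

# per-stage RNG streams derived from the one user-visible seed
.stageSeed <- function(config, stage) {
  offs <- c(genome = 0L, screen = 1L, reads = 2L)
  (config@seed + offs[[stage]]) %% .Machine$integer.max
}

#' Build a toy reference genome with stranded gene models
#'
#' Generates a single random A/C/G/T chromosome of `genomeLength` bases and
#' packs `nGenes` non-overlapping gene bodies onto it, separated by random
#' intergenic gaps. Each gene gets a random strand and is tiled, in
#' transcription order, into a 5'UTR, alternating exons and introns (2-4
#' exons), and a 3'UTR — the explicit UTRs make the orientation- and
#' region-dependent disruption rule fully testable. Deterministic for a
#' fixed `seed`.
#'
#' @param config a [SortedScreenConfig-class].
#' @return A [ToyGenome-class].
#' @examples
#' genome <- buildToyGenome(sortedScreenConfig(seed = 1L))
#' genome
#' @export
buildToyGenome <- function(config) {
  validObject(config)
  with_seed(.stageSeed(config, "genome"), {
    nG <- config@nGenes
    lens <- sample(seq(config@geneLengthRange[1L], config@geneLengthRange[2L]),
                   nG, replace = TRUE)
    slack <- config@genomeLength - sum(lens) - (nG + 1L)
    if (slack < 0L)
      stop("configuration error: gene_length_range incompatible with ",
           "genome_length (genes do not fit)")
    # distribute the non-genic bases over nG + 1 gaps (each >= 1)
    gaps <- as.integer(rmultinom(1L, slack, rep(1, nG + 1L))) + 1L
    starts <- integer(nG)
    pos <- 0L
    for (i in seq_len(nG)) {
      pos <- pos + gaps[i]
      starts[i] <- pos + 1L
      pos <- pos + lens[i]
    }
    strand <- sample(c("+", "-"), nG, replace = TRUE)
    ids <- sprintf("gene_%03d", seq_len(nG))
    genes <- GRanges("chr1",
                     IRanges(starts, width = lens),
                     strand = strand, gene_id = ids)
    regST <- regW <- integer(); regKind <- regGene <- regStrand <- character()
    for (i in seq_len(nG)) {
      L <- lens[i]
      u5 <- max(1L, as.integer(floor(0.10 * L)))
      u3 <- max(1L, as.integer(floor(0.15 * L)))
      inner <- L - u5 - u3
      nex <- sample(2:4, 1L)
      k <- 2L * nex - 1L            # exon/intron alternation
      if (inner < k) k <- 1L
      parts <- .randomComposition(inner, k)
      kinds <- c("five_prime_utr",
                 rep(c("exon", "intron"), length.out = k),
                 "three_prime_utr")
      widths <- c(u5, parts, u3)
      if (strand[i] == "-") { widths <- rev(widths); kinds <- rev(kinds) }
      st <- starts[i] + c(0L, cumsum(widths))[seq_along(widths)]
      regST <- c(regST, as.integer(st))
      regW <- c(regW, as.integer(widths))
      regKind <- c(regKind, kinds)
      regGene <- c(regGene, rep(ids[i], length(widths)))
      regStrand <- c(regStrand, rep(strand[i], length(widths)))
    }
    regions <- GRanges("chr1", IRanges(regST, width = regW),
                       strand = regStrand, gene_id = regGene,
                       kind = regKind)
    seq <- DNAStringSet(paste(sample(c("A", "C", "G", "T"),
                                     config@genomeLength, replace = TRUE),
                              collapse = ""))
    names(seq) <- "chr1"
    new("ToyGenome", sequences = seq, genes = genes, regions = regions)
  })
}

# disruptive-classification of raw insertion vectors against a genome;
# shared between the simulator (phenotype assignment) and classifySites()
.disruptiveGene <- function(chrom, pos, orient, genome) {
  sites <- GRanges(chrom, IRanges(pos, width = 1L))
  hits <- findOverlaps(sites, genome@regions, ignore.strand = TRUE)
  gene <- rep(NA_character_, length(sites))
  qh <- queryHits(hits); sh <- subjectHits(hits)
  kind <- genome@regions$kind[sh]
  sense <- orient[qh] == as.character(strand(genome@regions))[sh]
  ok <- sense & kind != "three_prime_utr"
  gene[qh[ok]] <- genome@regions$gene_id[sh[ok]]
  gene
}

#' Simulate a phenotype-sorted haploid gene-trap screen
#'
#' Each of `nCells` cells carries one insertion at a uniform genomic
#' position with a random cassette orientation. A cell's phenotype is
#' Gaussian noise plus the configured effect of the gene its insertion
#' disrupts (sense orientation, inside the gene body, outside the 3'UTR);
#' all other insertions — antisense, intergenic, 3'UTR — are carried
#' through with zero effect. Cells are ranked by phenotype, the top and
#' bottom `tailFraction` form the high/low pools (the sorted 5\% tails of
#' the fluorescence distribution), and `cellsSortedPerTail` cells are drawn
#' without replacement from each pool. Recovered insertions are collapsed
#' to unique sites per population by (chromosome, position, orientation).
#'
#' Insertion positions are drawn from `[1, genomeLength - readLength]` so
#' every site also supports junction-read emission.
#'
#' @param genome a [ToyGenome-class] built from the same configuration.
#' @param config a [SortedScreenConfig-class].
#' @return A list with elements `high` and `low` (unique insertion sites as
#'   width-1 `GRanges` with mcols `population` and `support`) and `truth`
#'   (a `DataFrame` of the simulated per-gene effects and the enrichment
#'   direction they imply).
#' @examples
#' cfg <- sortedScreenConfig(nCells = 20000L, cellsSortedPerTail = 800L,
#'                           seed = 7L)
#' sim <- simulateSortedScreen(buildToyGenome(cfg), cfg)
#' length(sim$high)
#' @export
simulateSortedScreen <- function(genome, config) {
  validObject(config)
  nTail <- floor(config@tailFraction * config@nCells)
  if (nTail < 1L)
    stop("simulation error: empty tail after sorting")
  with_seed(.stageSeed(config, "screen"), {
    n <- config@nCells
    maxPos <- config@genomeLength - config@readLength
    if (is.na(config@intergenicFraction)) {
      pos <- sample.int(maxPos, n, replace = TRUE)
    } else {
      genic <- GenomicRanges::intersect(GRanges("chr1", IRanges(1L, maxPos)),
                                        reduce(genome@genes,
                                               ignore.strand = TRUE),
                                        ignore.strand = TRUE)
      inter <- GenomicRanges::setdiff(GRanges("chr1", IRanges(1L, maxPos)),
                                      genic, ignore.strand = TRUE)
      isInter <- runif(n) < config@intergenicFraction
      pos <- integer(n)
      pos[!isInter] <- .sampleWithin(genic, sum(!isInter))
      pos[isInter] <- .sampleWithin(inter, sum(isInter))
    }
    # orientation: per-gene sense with prob orientationProbSense in genes,
    # uniform forward/reverse outside them
    orient <- sample(c("+", "-"), n, replace = TRUE)
    if (config@orientationProbSense != 0.5) {
      bodyHit <- findOverlaps(GRanges("chr1", IRanges(pos, width = 1L)),
                              genome@genes, ignore.strand = TRUE,
                              select = "first")
      inGene <- !is.na(bodyHit)
      gstr <- as.character(strand(genome@genes))[bodyHit[inGene]]
      sense <- runif(sum(inGene)) < config@orientationProbSense
      orient[inGene] <- ifelse(sense, gstr, chartr("+-", "-+", gstr))
    }
    gene <- .disruptiveGene("chr1", pos, orient, genome)
    eff <- rep(0, n)
    hasEff <- !is.na(gene) & gene %in% names(config@geneEffects)
    eff[hasEff] <- config@geneEffects[gene[hasEff]]
    phen <- eff + rnorm(n, 0, config@phenotypeNoiseSd)
    ord <- order(phen)
    lowPool <- ord[seq_len(nTail)]
    highPool <- ord[seq.int(n - nTail + 1L, n)]
    take <- function(pool, label) {
      keep <- sample(pool, config@cellsSortedPerTail)
      .collapseRaw("chr1", pos[keep], orient[keep], label)
    }
    high <- take(highPool, "high")
    low <- take(lowPool, "low")
    effTab <- config@geneEffects
    truth <- DataFrame(
      gene_id = genome@genes$gene_id,
      effect = ifelse(genome@genes$gene_id %in% names(effTab),
                      effTab[genome@genes$gene_id], 0),
      direction = "none")
    truth$direction[truth$effect > 0] <- "enriched_high"
    truth$direction[truth$effect < 0] <- "enriched_low"
    list(high = high, low = low, truth = truth)
  })
}

# sample k positions uniformly from the bases covered by a GRanges
.sampleWithin <- function(gr, k) {
  if (k == 0L) return(integer())
  w <- width(gr)
  idx <- sample.int(length(gr), k, replace = TRUE, prob = w)
  start(gr)[idx] + as.integer(floor(runif(k) * w[idx]))
}

# dedupe raw (chrom, pos, orient) triples into a sorted site GRanges
.collapseRaw <- function(chrom, pos, orient, population) {
  chrom <- rep_len(chrom, length(pos))
  key <- paste(chrom, pos, orient)
  tab <- table(key)
  first <- !duplicated(key)
  gr <- GRanges(chrom[first], IRanges(pos[first], width = 1L),
                strand = orient[first])
  gr$population <- population
  gr$support <- as.integer(tab[key[first]])
  .sortSites(gr)
}

# deterministic site order: chromosome, position, then strand
.sortSites <- function(gr) {
  gr[order(as.character(seqnames(gr)), start(gr),
           as.character(strand(gr)))]
}

#' Emit gene-trap junction reads for insertion sites
#'
#' One read per site, taken from the reference window of `readLength` bases
#' starting at the insertion position on the forward strand; for
#' reverse-orientation sites the read is the reverse complement of that
#' window, so mapping recovers the site's forward-strand coordinate with
#' the matched strand as its orientation. Per read, 0, 1 or 2 substitutions
#' are injected with the probabilities in `mismatchRate`. The read name
#' encodes the true site (`chrom|position|orientation|n_mismatches`) for
#' round-trip checks.
#'
#' @param sites a width-1 `GRanges` of insertion sites.
#' @param genome a [ToyGenome-class].
#' @param config a [SortedScreenConfig-class] (read length, mismatch
#'   probabilities, seed).
#' @return A named `DNAStringSet` of junction reads.
#' @export
emitJunctionReads <- function(sites, genome, config) {
  validObject(config)
  L <- config@readLength
  chroms <- as.character(seqnames(sites))
  lens <- width(genome@sequences)[match(chroms, names(genome@sequences))]
  if (any(is.na(lens)) || any(start(sites) < 1L) ||
      any(start(sites) + L - 1L > lens))
    stop("coordinate error: site window outside the genome")
  with_seed(.stageSeed(config, "reads"), {
    reads <- DNAStringSet(rep("", length(sites)))
    for (chrom in unique(chroms)) {
      i <- which(chroms == chrom)
      v <- Views(genome@sequences[[chrom]],
                 start = start(sites)[i], width = L)
      reads[i] <- as(v, "DNAStringSet")
    }
    rev <- as.character(strand(sites)) == "-"
    reads[rev] <- reverseComplement(reads[rev])
    nmm <- sample(0:2, length(sites), replace = TRUE,
                  prob = config@mismatchRate)
    for (i in which(nmm > 0L)) {
      chars <- strsplit(as.character(reads[[i]]), "")[[1L]]
      at <- sample.int(L, nmm[i])
      for (p in at)
        chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
      reads[[i]] <- DNAString(paste(chars, collapse = ""))
    }
    names(reads) <- sprintf("read%06d|%s|%d|%s|%d",
                            seq_along(sites), chroms, start(sites),
                            as.character(strand(sites)), nmm)
    reads
  })
}
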