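#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<-
#' @importFrom GenomicRanges GRanges seqnames start end strand granges
#' @importFrom IRanges IRanges
#' @importFrom Biostrings DNAStringSet
NULL

#' Configuration of a synthetic phenotype-sorted gene-trap screen
#'
#' A `SortedScreenConfig` holds every generative parameter of the synthetic
#' screen: the toy genome layout, the mutagenized cell pool, the FACS tail
#' sorting, the phenotype model, and the junction-read emission. Defaults
#' describe a scaled-down screen: a 150 kb genome carrying 50 genes,
#' 2e5 mutagenized cells, the lowest and highest 5\% of the phenotype
#' distribution sorted, and 8000 cells recovered per sorted tail.
#'
#' The phenotype model is Gaussian-additive: every cell carries exactly one
#' insertion; a cell's phenotype is `baseline + effect + noise`, where
#' `effect = geneEffects[g]` iff the insertion is disruptive for gene `g`
#' (sense orientation, inside the gene body, outside the 3'UTR) and 0
#' otherwise, and the noise is `N(0, phenotypeNoiseSd)`.
#'
#' @slot nGenes number of genes in the toy genome.
#' @slot genomeLength total genome length in bases (single chromosome).
#' @slot geneLengthRange integer(2), min and max gene-body length in bases.
#' @slot nCells number of mutagenized cells carried into the sort.
#' @slot tailFraction fraction of cells in each sorted tail (0 < f < 0.5).
#' @slot cellsSortedPerTail cells recovered from each tail
#'   (must not exceed `tailFraction * nCells`).
#' @slot phenotypeNoiseSd standard deviation of the per-cell phenotype
#'   noise, in arbitrary fluorescence units.
#' @slot geneEffects named numeric; additive phenotype shift (fluorescence
#'   units) applied when a cell's insertion disrupts the named gene.
#' @slot intergenicFraction fraction of insertions placed outside gene
#'   bodies; `NA` means uniform over the genome.
#' @slot orientationProbSense probability that an in-gene insertion is in
#'   the sense orientation relative to its gene.
#' @slot readLength junction-read length in bases.
#' @slot mismatchRate numeric(3), probabilities of injecting 0, 1 or 2
#'   substitutions per emitted read.
#' @slot seed integer seed; all stochastic stages derive their streams
#'   from it, so a fixed seed gives byte-identical outputs.
#'
#' @seealso [sortedScreenConfig()], [buildToyGenome()],
#'   [simulateSortedScreen()]
#' @export
setClass("SortedScreenConfig",
  representation(
    nGenes = "integer",
    genomeLength = "integer",
    geneLengthRange = "integer",
    nCells = "integer",
    tailFraction = "numeric",
    cellsSortedPerTail = "integer",
    phenotypeNoiseSd = "numeric",
    geneEffects = "numeric",
    intergenicFraction = "numeric",
    orientationProbSense = "numeric",
    readLength = "integer",
    mismatchRate = "numeric",
    seed = "integer"
  )
)

setValidity("SortedScreenConfig", function(object) {
  msg <- character()
  if (object@nGenes < 1L) msg <- c(msg, "nGenes must be >= 1")
  if (length(object@geneLengthRange) != 2L ||
      any(object@geneLengthRange < 1L) || diff(object@geneLengthRange) < 0L)
    msg <- c(msg, "geneLengthRange must be two increasing positive lengths")
  if (!(object@tailFraction > 0 && object@tailFraction < 0.5))
    msg <- c(msg, "tailFraction must lie in (0, 0.5)")
  if (object@cellsSortedPerTail > floor(object@tailFraction * object@nCells))
    msg <- c(msg, "cellsSortedPerTail exceeds tailFraction * nCells")
  if (object@cellsSortedPerTail < 1L)
    msg <- c(msg, "cellsSortedPerTail must be >= 1")
  if (!is.na(object@intergenicFraction) &&
      (object@intergenicFraction < 0 || object@intergenicFraction > 1))
    msg <- c(msg, "intergenicFraction must be in [0, 1] or NA")
  if (object@orientationProbSense < 0 || object@orientationProbSense > 1)
    msg <- c(msg, "orientationProbSense must be in [0, 1]")
  if (object@phenotypeNoiseSd <= 0)
    msg <- c(msg, "phenotypeNoiseSd must be > 0")
  if (length(object@mismatchRate) != 3L || any(object@mismatchRate < 0) ||
      abs(sum(object@mismatchRate) - 1) > 1e-9)
    msg <- c(msg, "mismatchRate must be 3 probabilities summing to 1")
  if (object@readLength < 1L) msg <- c(msg, "readLength must be >= 1")
  if (length(object@geneEffects) &&
      is.null(names(object@geneEffects)))
    msg <- c(msg, "geneEffects must be named by gene_id")
  if (is.na(object@seed)) msg <- c(msg, "seed is required")
  if (length(msg)) msg else TRUE
})

#' Construct a SortedScreenConfig
#'
#' @param nGenes,genomeLength,geneLengthRange,nCells,tailFraction,cellsSortedPerTail,phenotypeNoiseSd,geneEffects,intergenicFraction,orientationProbSense,readLength,mismatchRate,seed
#'   see the slot documentation in [SortedScreenConfig-class].
#'
#' @return A validated `SortedScreenConfig`.
#' @examples
#' cfg <- sortedScreenConfig(seed = 1L, geneEffects = c(gene_007 = 8))
#' cfg
#' @export
sortedScreenConfig <- function(nGenes = 50L,
                               genomeLength = 150000L,
                               geneLengthRange = c(1500L, 3000L),
                               nCells = 200000L,
                               tailFraction = 0.05,
                               cellsSortedPerTail = 8000L,
                               phenotypeNoiseSd = 1,
                               geneEffects = numeric(),
                               intergenicFraction = NA_real_,
                               orientationProbSense = 0.5,
                               readLength = 50L,
                               mismatchRate = c(0.9, 0.1, 0),
                               seed) {
  if (missing(seed))
    stop("a seed is required for every stochastic operation")
  new("SortedScreenConfig",
      nGenes = as.integer(nGenes),
      genomeLength = as.integer(genomeLength),
      geneLengthRange = as.integer(geneLengthRange),
      nCells = as.integer(nCells),
      tailFraction = as.numeric(tailFraction),
      cellsSortedPerTail = as.integer(cellsSortedPerTail),
      phenotypeNoiseSd = as.numeric(phenotypeNoiseSd),
      geneEffects = geneEffects,
      intergenicFraction = as.numeric(intergenicFraction),
      orientationProbSense = as.numeric(orientationProbSense),
      readLength = as.integer(readLength),
      mismatchRate = as.numeric(mismatchRate),
      seed = as.integer(seed))
}

#' A toy reference genome with gene models
#'
#' Bundles the chromosome sequences with the gene annotation. Gene bodies
#' are 1-based closed intervals (GRanges convention); the `regions` track
#' tiles each gene body without gaps or overlap into 5'UTR, exon, intron
#' and 3'UTR features. Every gene carries an explicit 5'UTR and 3'UTR so
#' the orientation- and region-dependent disruption rule is exercised.
#'
#' @slot sequences a [Biostrings::DNAStringSet] of chromosome sequences.
#' @slot genes a `GRanges` of gene bodies with an mcol `gene_id`.
#' @slot regions a `GRanges` of gene sub-features with mcols `gene_id` and
#'   `kind` (one of `five_prime_utr`, `exon`, `intron`, `three_prime_utr`).
#'
#' @seealso [buildToyGenome()], [geneModels()], [geneRegions()]
#' @export
setClass("ToyGenome",
  representation(
    sequences = "DNAStringSet",
    genes = "GRanges",
    regions = "GRanges"
  )
)

setValidity("ToyGenome", function(object) {
  msg <- character()
  if (is.null(object@genes$gene_id))
    msg <- c(msg, "genes must carry a gene_id mcol")
  if (is.null(object@regions$gene_id) || is.null(object@regions$kind))
    msg <- c(msg, "regions must carry gene_id and kind mcols")
  kinds <- c("five_prime_utr", "exon", "intron", "three_prime_utr")
  if (length(object@regions) && !all(object@regions$kind %in% kinds))
    msg <- c(msg, "unknown region kind")
  if (!all(as.character(seqnames(object@genes)) %in%
           names(object@sequences)))
    msg <- c(msg, "gene on a chromosome absent from the sequences")
  lens <- width(object@sequences)
  names(lens) <- names(object@sequences)
  bad <- end(object@genes) > lens[as.character(seqnames(object@genes))]
  if (any(bad)) msg <- c(msg, "gene extends past its chromosome end")
  # regions must tile each gene body exactly (vectorized over genes)
  if (length(object@genes) && length(object@regions)) {
    ord <- order(object@regions$gene_id, start(object@regions))
    gid <- object@regions$gene_id[ord]
    rs <- start(object@regions)[ord]
    re <- end(object@regions)[ord]
    sums <- rowsum(re - rs + 1L, gid)
    sumw <- sums[match(object@genes$gene_id, rownames(sums)), 1L]
    minS <- tapply(rs, gid, min)[object@genes$gene_id]
    maxE <- tapply(re, gid, max)[object@genes$gene_id]
    n <- length(gid)
    within <- gid[-1L] == gid[-n]
    contiguous <- all(rs[-1L][within] == re[-n][within] + 1L)
    if (anyNA(sumw) || any(sumw != width(object@genes)) ||
        any(minS != start(object@genes)) ||
        any(maxE != end(object@genes)) || !contiguous)
      msg <- c(msg, "regions do not tile their gene bodies")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn ToyGenome-class chromosome sequences as a `DNAStringSet`.
#' @param genome a `ToyGenome`.
#' @export
genomeSequences <- function(genome) genome@sequences

#' @describeIn ToyGenome-class gene bodies as a stranded `GRanges`.
#' @export
geneModels <- function(genome) genome@genes

#' @describeIn ToyGenome-class gene sub-features (5'UTR/exon/intron/3'UTR).
#' @export
geneRegions <- function(genome) genome@regions

setMethod("show", "SortedScreenConfig", function(object) {
  cat("SortedScreenConfig\n")
  cat(sprintf("  genome: %d genes over %d bp (gene bodies %d-%d bp)\n",
              object@nGenes, object@genomeLength,
              object@geneLengthRange[1L], object@geneLengthRange[2L]))
  cat(sprintf("  screen: %d cells, %.1f%% tails, %d sorted per tail\n",
              object@nCells, 100 * object@tailFraction,
              object@cellsSortedPerTail))
  cat(sprintf("  phenotype: noise sd %.3g, %d gene effect(s)\n",
              object@phenotypeNoiseSd, length(object@geneEffects)))
  cat(sprintf("  reads: %d bp, mismatch probs %s\n", object@readLength,
              paste(format(object@mismatchRate), collapse = "/")))
  cat(sprintf("  seed: %d\n", object@seed))
})

setMethod("show", "ToyGenome", function(object) {
  cat(sprintf("ToyGenome: %d chromosome(s), %d bp total, %d gene(s)\n",
              length(object@sequences), sum(width(object@sequences)),
              length(object@genes)))
})
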