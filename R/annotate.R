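#' @importFrom GenomicRanges findOverlaps
NULL

# accept a ToyGenome or a regions GRanges (gene_id + kind mcols)
.asRegions <- function(models) {
  if (is(models, "ToyGenome")) return(models@regions)
  if (is(models, "GRanges")) {
    if (is.null(models$gene_id) || is.null(models$kind))
      stop("region models need gene_id and kind mcols")
    return(models)
  }
  stop("models must be a ToyGenome or a regions GRanges")
}

#' Classify insertion sites against gene models
#'
#' Tests every site against all overlapping gene bodies. Per (site, gene)
#' pair it reports the region hit (5'UTR, exon, intron or 3'UTR — the
#' regions tile the body, so exactly one per gene), whether the insertion
#' is in the sense orientation (cassette strand equals gene strand), and
#' whether it is disruptive. A gene-trap disrupts a gene only when
#' integrated in the sense orientation within the gene body's 5'UTR, exon
#' or intron; 3'UTR hits are annotated but never disruptive (the trap's
#' splice acceptor lies downstream of the coding sequence), and antisense
#' hits are never disruptive. Sites overlapping no gene body are
#' intergenic; sites on a chromosome absent from the annotation are
#' classified intergenic with a warning.
#'
#' @param sites a width-1 `GRanges` of insertion sites (strand = cassette
#'   orientation), with an optional `population` mcol.
#' @param models a [ToyGenome-class] or a regions `GRanges` with mcols
#'   `gene_id` and `kind`.
#' @return A `DataFrame` with one row per (site, overlapping gene) and one
#'   row per intergenic site (`gene_id = NA`): columns `site`, `chromosome`,
#'   `position`, `orientation`, `population`, `gene_id`, `region`, `sense`,
#'   `disruptive`. `metadata(.)` records the gene universe and the
#'   population label.
#' @examples
#' cfg <- sortedScreenConfig(nCells = 20000L, cellsSortedPerTail = 800L,
#'                           seed = 7L)
#' genome <- buildToyGenome(cfg)
#' sim <- simulateSortedScreen(genome, cfg)
#' ann <- classifySites(sim$high, genome)
#' table(ann$disruptive)
#' @export
classifySites <- function(sites, models) {
  regions <- .asRegions(models)
  chromKnown <- unique(as.character(seqnames(regions)))
  siteChrom <- as.character(seqnames(sites))
  if (length(sites) && any(!siteChrom %in% chromKnown))
    warning("site(s) on chromosome(s) absent from the annotation ",
            "classified as intergenic: ",
            paste(unique(siteChrom[!siteChrom %in% chromKnown]),
                  collapse = ", "))
  pop <- if (is.null(sites$population)) rep(NA_character_, length(sites))
         else sites$population
  # the absent-chromosome case is handled (and warned about) above
  hits <- withCallingHandlers(
    findOverlaps(sites, regions, ignore.strand = TRUE),
    warning = function(w) {
      if (grepl("sequence levels in common", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  qh <- queryHits(hits); sh <- subjectHits(hits)
  orphan <- setdiff(seq_along(sites), unique(qh))
  ori <- as.character(strand(sites))
  sense <- ori[qh] == as.character(strand(regions))[sh]
  kind <- regions$kind[sh]
  ann <- DataFrame(
    site = c(qh, orphan),
    chromosome = c(siteChrom[qh], siteChrom[orphan]),
    position = c(start(sites)[qh], start(sites)[orphan]),
    orientation = c(ori[qh], ori[orphan]),
    population = c(pop[qh], pop[orphan]),
    gene_id = c(regions$gene_id[sh], rep(NA_character_, length(orphan))),
    region = c(kind, rep(NA_character_, length(orphan))),
    sense = c(sense, rep(NA, length(orphan))),
    disruptive = c(sense & kind != "three_prime_utr",
                   rep(FALSE, length(orphan))))
  ann <- ann[order(ann$site, ann$gene_id), ]
  rownames(ann) <- NULL
  metadata(ann)$gene_ids <- unique(regions$gene_id)
  pops <- unique(pop[!is.na(pop)])
  metadata(ann)$population <- if (length(pops) == 1L) pops else NA_character_
  ann
}

#' Tabulate per-gene disruptive insertion counts for two populations
#'
#' For each gene `g`, `a` is the number of unique disruptive insertion
#' sites for `g` in the high population and `b` the same in the low
#' population. `H` and `L` are the total unique disruptive sites across all
#' genes in each population — the normalizers of the mutational index. A
#' site disruptive for k overlapping genes contributes k to the per-gene
#' tallies but only once to the totals, so overlapping genes never inflate
#' the normalizer; with disjoint gene models `sum(a) == H` exactly.
#' Antisense, 3'UTR and intergenic sites never enter `a`, `b`, `H` or `L`.
#' Genes with no disruptive sites are retained with zero counts.
#'
#' @param annotationsHigh,annotationsLow `DataFrame`s from [classifySites()]
#'   for the high and low populations, annotated against the same models.
#' @return A `DataFrame` with columns `gene_id`, `a`, `b`, `H`, `L`
#'   (one row per gene in the annotation's gene universe).
#' @export
tabulateCounts <- function(annotationsHigh, annotationsLow) {
  popH <- metadata(annotationsHigh)$population
  popL <- metadata(annotationsLow)$population
  if (!is.null(popH) && !is.null(popL) &&
      !is.na(popH) && !is.na(popL) && popH == popL)
    stop("input error: both inputs carry the same population label")
  for (x in list(annotationsHigh, annotationsLow)) {
    p <- x$population[!is.na(x$population)]
    if (length(unique(p)) > 1L)
      stop("input error: mixed population labels within one input")
  }
  genes <- union(metadata(annotationsHigh)$gene_ids,
                 metadata(annotationsLow)$gene_ids)
  countFor <- function(ann) {
    d <- ann[ann$disruptive %in% TRUE, , drop = FALSE]
    per <- table(factor(d$gene_id, levels = genes))
    list(per = as.integer(per), total = length(unique(d$site)))
  }
  high <- countFor(annotationsHigh)
  low <- countFor(annotationsLow)
  DataFrame(gene_id = genes,
            a = high$per, b = low$per,
            H = high$total, L = low$total)
}
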