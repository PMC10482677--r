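#' @importFrom utils write.table read.table packageVersion
#' @importFrom rtracklayer import export
NULL

#' Write a toy genome as FASTA plus annotation
#'
#' Writes the chromosome sequences as FASTA, the gene models as GTF
#' (1-based inclusive coordinates; features `gene`, `exon`,
#' `five_prime_utr`, `three_prime_utr` and — explicitly, unlike most
#' annotations — `intron`), and as a simplified 0-based half-open TSV.
#'
#' @param genome a [ToyGenome-class].
#' @param fastaPath,gtfPath,tsvPath output paths; `NULL` skips that file.
#' @return Invisibly, the paths written.
#' @export
writeToyGenome <- function(genome, fastaPath = NULL, gtfPath = NULL,
                           tsvPath = NULL) {
  written <- character()
  if (!is.null(fastaPath)) {
    writeXStringSet(genome@sequences, fastaPath)
    written <- c(written, fastaPath)
  }
  if (!is.null(gtfPath)) {
    g <- genome@genes
    g$type <- "gene"
    r <- genome@regions
    r$type <- r$kind
    r$kind <- NULL
    all <- c(g, r)
    all$source <- "hapscreen"
    export(all, gtfPath, format = "gtf")
    written <- c(written, gtfPath)
  }
  if (!is.null(tsvPath)) {
    r <- genome@regions
    df <- data.frame(chromosome = as.character(seqnames(r)),
                     start = start(r) - 1L,   # 0-based half-open
                     end = end(r),
                     gene_id = r$gene_id,
                     strand = as.character(strand(r)),
                     kind = r$kind)
    write.table(df, tsvPath, sep = "\t", quote = FALSE, row.names = FALSE)
    written <- c(written, tsvPath)
  }
  invisible(written)
}

#' Read gene models from GTF or the simplified TSV annotation
#'
#' GTF coordinates (1-based inclusive) are used directly; the simplified
#' TSV is 0-based half-open and converted on read. Gene bodies are derived
#' as the per-gene range of the region features.
#'
#' @param path a GTF (`.gtf`) or TSV annotation file.
#' @return A list with `genes` and `regions` `GRanges`, the annotation
#'   slots of a [ToyGenome-class].
#' @export
readAnnotation <- function(path) {
  if (grepl("\\.gtf$", path, ignore.case = TRUE)) {
    gr <- import(path, format = "gtf")
    regions <- gr[gr$type %in% c("five_prime_utr", "exon", "intron",
                                 "three_prime_utr")]
    regions$kind <- as.character(regions$type)
  } else {
    df <- read.table(path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
    regions <- GRanges(df$chromosome,
                       IRanges(df$start + 1L, df$end),
                       strand = df$strand,
                       gene_id = df$gene_id, kind = df$kind)
  }
  mcols(regions) <- mcols(regions)[, c("gene_id", "kind")]
  rr <- split(regions, regions$gene_id)
  genes <- unlist(range(rr))
  genes$gene_id <- names(genes)
  names(genes) <- NULL
  list(genes = genes, regions = sort(regions, ignore.strand = TRUE))
}

#' Write insertion sites as BED6
#'
#' Six columns: chrom, 0-based start, end, name = population label,
#' score = 0, strand = cassette orientation.
#'
#' @param sites a width-1 `GRanges` with a `population` mcol.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeInsertionBed <- function(sites, path) {
  bed <- granges(sites)
  bed$name <- sites$population
  bed$score <- 0L
  export(bed, path, format = "bed")
  invisible(path)
}

#' Read insertion sites from BED6
#'
#' @param path a BED6 file written by [writeInsertionBed()] (name column =
#'   population label).
#' @return A width-1 `GRanges` with `population` and `support` mcols.
#' @export
readInsertionBed <- function(path) {
  lines <- readLines(path)
  nfield <- lengths(strsplit(lines, "\t", fixed = TRUE))
  if (any(nfield != 6L))
    stop("input error: malformed BED line(s): ",
         paste(which(nfield != 6L), collapse = ", "))
  gr <- import(path, format = "bed")
  out <- granges(gr)
  out$population <- gr$name
  out$support <- 1L
  out
}

#' Write junction reads as FASTQ
#'
#' Constant quality (`I`) per base; the read names carry the encoded truth
#' from [emitJunctionReads()].
#'
#' @param reads a named `DNAStringSet`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeReadsFastq <- function(reads, path) {
  writeXStringSet(reads, path, format = "fastq")
  invisible(path)
}

#' Read junction reads from FASTQ
#'
#' @param path a FASTQ file.
#' @return A named `DNAStringSet`.
#' @export
readReadsFastq <- function(path) {
  readDNAStringSet(path, format = "fastq")
}

# deterministic TSV writer for DataFrame results
.writeTsv <- function(x, path) {
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
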