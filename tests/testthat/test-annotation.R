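test_that("sense/antisense and region rules drive the disruptive flag", {
  g <- makeTinyGenome()
  # geneA: + strand, 5'UTR 21-28, exon 29-44, intron 45-52, 3'UTR 53-60
  sites <- makeSites(c(30L, 30L, 47L, 55L, 24L, 10L),
                     c("+", "-", "+", "+", "+", "+"))
  ann <- classifySites(sites, g)
  pick <- function(i) ann[ann$site == i, ]
  expect_true(pick(1)$disruptive)                     # sense exon
  expect_identical(pick(1)$region, "exon")
  expect_false(pick(2)$disruptive)                    # antisense exon
  expect_true(pick(3)$disruptive)                     # sense intron
  expect_false(pick(4)$disruptive)                    # sense 3'UTR
  expect_identical(pick(4)$region, "three_prime_utr")
  expect_true(pick(5)$disruptive)                     # sense 5'UTR
  expect_true(is.na(pick(6)$gene_id))                 # intergenic
  # disruptive implies sense and implies region != 3'UTR
  d <- ann[ann$disruptive %in% TRUE, ]
  expect_true(all(d$sense))
  expect_true(all(d$region != "three_prime_utr"))
})

test_that("minus-strand genes use their own strand for the sense test", {
  g <- makeTinyGenome()
  # geneB: - strand, exon 77-82; sense there means cassette on -
  ann <- classifySites(makeSites(c(80L, 80L), c("-", "+")), g)
  expect_true(ann$disruptive[ann$site == 1])
  expect_false(ann$disruptive[ann$site == 2])
  # 3'UTR of geneB is 71-76: never disruptive even in sense
  ann3 <- classifySites(makeSites(73L, "-"), g)
  expect_identical(ann3$region, "three_prime_utr")
  expect_false(ann3$disruptive)
})

test_that("gene-body boundaries behave half-open at both ends", {
  g <- makeTinyGenome()
  # body 21-60: first base in, one before out; last base in, one past out
  ann <- classifySites(makeSites(c(20L, 21L, 60L, 61L), "+"), g)
  expect_true(is.na(ann$gene_id[ann$site == 1]))
  expect_identical(ann$gene_id[ann$site == 2], "geneA")
  expect_identical(ann$gene_id[ann$site == 3], "geneA")
  expect_true(is.na(ann$gene_id[ann$site == 4]))
  # the TSV annotation round-trips the same intervals (0-based half-open)
  tsv <- tempfile(fileext = ".tsv")
  writeToyGenome(g, tsvPath = tsv)
  df <- read.table(tsv, header = TRUE, sep = "\t")
  expect_identical(min(df$start[df$gene_id == "geneA"]), 20L)
  expect_identical(max(df$end[df$gene_id == "geneA"]), 60L)
  back <- readAnnotation(tsv)
  ann2 <- classifySites(makeSites(c(20L, 21L, 60L, 61L), "+"),
                        back$regions)
  expect_identical(ann2$gene_id, ann$gene_id)
})

test_that("sites on unannotated chromosomes fall back to intergenic with a warning", {
  g <- makeTinyGenome()
  expect_warning(ann <- classifySites(makeSites(5L, "+", chrom = "chrX"),
                                      g),
                 "absent")
  expect_true(is.na(ann$gene_id))
  expect_false(ann$disruptive)
})

test_that("classification is invariant to site and model order", {
  g <- buildToyGenome(smallConfig(seed = 53L))
  sim <- simulateSortedScreen(g, smallConfig(seed = 53L))
  sites <- sim$high
  a1 <- classifySites(sites, g)
  a2 <- classifySites(sites, geneRegions(g)[sample(length(geneRegions(g)))])
  key <- function(a) {
    k <- paste(a$position, a$orientation, a$gene_id, a$region,
               a$disruptive)
    sort(k)
  }
  expect_identical(key(a1), key(a2))
})

test_that("interval classification agrees with a naive double loop", {
  g <- makeTinyGenome()
  set.seed(3)
  pos <- sample.int(100L, 60L, replace = TRUE)
  ori <- sample(c("+", "-"), 60L, replace = TRUE)
  ann <- classifySites(makeSites(pos, ori), g)
  reg <- geneRegions(g)
  for (i in seq_along(pos)) {
    rows <- ann[ann$site == i, ]
    hits <- which(start(reg) <= pos[i] & pos[i] <= end(reg))
    if (!length(hits)) {
      expect_true(is.na(rows$gene_id))
    } else {
      for (h in hits) {
        r <- rows[rows$gene_id == reg$gene_id[h], ]
        expect_identical(r$region, reg$kind[h])
        expect_identical(r$sense,
                         ori[i] == as.character(strand(reg))[h])
      }
    }
  }
})

test_that("single-gene bookkeeping gives (a, H, b, L) = (4, 4, 1, 1)", {
  g <- makeTinyGenome()
  high <- classifySites(makeSites(c(22L, 30L, 40L, 47L), "+", "high"), g)
  low <- classifySites(makeSites(35L, "+", "low"), g)
  ct <- tabulateCounts(high, low)
  row <- ct[ct$gene_id == "geneA", ]
  expect_identical(c(row$a, row$H, row$b, row$L), c(4L, 4L, 1L, 1L))
  # geneB retained with zero counts
  expect_identical(ct$a[ct$gene_id == "geneB"], 0L)
})

test_that("a hand-built 12-site fixture matches its manual tally", {
  g <- makeTinyGenome()
  # high: geneA disruptive at 22,30,47 (+); geneA 3'UTR 55 (+); geneA
  # antisense 33 (-); geneB disruptive at 78,80 (-); geneB 5'UTR 85 (-)
  high <- classifySites(
    makeSites(c(22L, 30L, 47L, 55L, 33L, 78L, 80L, 85L),
              c("+", "+", "+", "+", "-", "-", "-", "-"), "high"), g)
  # low: geneA disruptive 29 (+); geneB disruptive 77 (-); intergenic 5;
  # geneB antisense 79 (+)
  low <- classifySites(
    makeSites(c(29L, 77L, 5L, 79L),
              c("+", "-", "+", "+"), "low"), g)
  ct <- tabulateCounts(high, low)
  expect_identical(ct$a[ct$gene_id == "geneA"], 3L)
  expect_identical(ct$a[ct$gene_id == "geneB"], 3L)  # 78, 80, 85
  expect_identical(ct$b[ct$gene_id == "geneA"], 1L)
  expect_identical(ct$b[ct$gene_id == "geneB"], 1L)
  expect_identical(unique(ct$H), 6L)
  expect_identical(unique(ct$L), 2L)
})

test_that("an antisense-only gene counts zero despite overlapping sites", {
  g <- makeTinyGenome()
  high <- classifySites(makeSites(c(30L, 35L, 40L), "-", "high"), g)
  low <- classifySites(makeSites(c(31L, 36L), "-", "low"), g)
  ct <- tabulateCounts(high, low)
  expect_identical(ct$a[ct$gene_id == "geneA"], 0L)
  expect_identical(ct$b[ct$gene_id == "geneA"], 0L)
})

test_that("disjoint gene models conserve sum(a) == H on generator output", {
  cfg <- smallConfig(seed = 59L)
  g <- buildToyGenome(cfg)
  sim <- simulateSortedScreen(g, cfg)
  ct <- tabulateCounts(classifySites(sim$high, g),
                       classifySites(sim$low, g))
  expect_identical(sum(ct$a), unique(ct$H))
  expect_identical(sum(ct$b), unique(ct$L))
})

test_that("mixed population labels within one input are rejected", {
  g <- makeTinyGenome()
  mixed <- makeSites(c(30L, 31L), "+", population = c("high", "low"))
  annM <- classifySites(mixed, g)
  annL <- classifySites(makeSites(35L, "+", "low"), g)
  expect_error(tabulateCounts(annM, annL), "mixed population")
})
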