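#' @importFrom stats dhyper
NULL

#' Mutational index of a gene between sorted populations
#'
#' The mutational index (MI) is the leave-one-out odds ratio of a gene's
#' unique, disruptive (sense, gene-body) insertion count between the high
#' and low sorted populations, each count normalized by the total of the
#' *other* disruptive insertions in its population:
#' \deqn{MI = \frac{a/(H-a)}{b/(L-b)}}
#' where `a`, `b` are the gene's disruptive insertions in the high and low
#' populations and `H`, `L` the population totals. MI > 1 means disruptions
#' of the gene accumulate in the high tail.
#'
#' Zero counts are kept exact rather than smoothed: `a = 0` gives MI = 0,
#' `b = 0` with `a > 0` gives MI = +Inf, and `a = b = 0` gives NaN
#' (undefined; such genes are excluded from fishtail tables). A
#' Haldane-style pseudocount is available separately for log-scale
#' displays; see [fishtailTable()].
#'
#' @param a,b disruptive insertion counts of the gene in the high and low
#'   populations (vectorized).
#' @param H,L total disruptive insertion counts in each population.
#' @return Numeric vector of mutational indices in `[0, Inf]` (NaN when
#'   `a = b = 0`).
#' @examples
#' mutationalIndex(10, 1000, 5, 2000)   # (10/990)/(5/1995) = 4.0303...
#' @export
mutationalIndex <- function(a, H, b, L) {
  if (any(a < 0 | b < 0 | a > H | b > L))
    stop("input error: counts must satisfy 0 <= a <= H and 0 <= b <= L")
  n <- max(length(a), length(H), length(b), length(L))
  a <- rep_len(a, n); H <- rep_len(H, n)
  b <- rep_len(b, n); L <- rep_len(L, n)
  mi <- rep(NaN, length(a))
  both0 <- a == 0 & b == 0
  mi[!both0 & a == 0] <- 0
  posInf <- !both0 & a > 0 & b == 0
  mi[posInf] <- Inf
  gen <- !both0 & a > 0 & b > 0
  mi[gen] <- (a[gen] / (H[gen] - a[gen])) / (b[gen] / (L[gen] - b[gen]))
  mi
}

# Haldane-smoothed MI used only for log2 displays and screen comparisons:
# +0.5 on the gene's own counts, totals untouched
.haldaneMI <- function(a, H, b, L) {
  ((a + 0.5) / (H - a)) / ((b + 0.5) / (L - b))
}

#' Two-sided Fisher's exact test on insertion counts
#'
#' Exact two-sided P value for the 2x2 table `[[a, H-a], [b, L-b]]` —
#' the gene's disruptive insertions against all other disruptive
#' insertions in each population, the same table whose odds ratio is the
#' mutational index. Sidedness follows the minimum-likelihood convention:
#' P is the sum of the hypergeometric probabilities of all tables with the
#' same margins whose probability does not exceed that of the observed
#' table (relative tolerance 1e-7 on the inclusion comparison, applied in
#' log space for numerical stability).
#'
#' @param a,b the gene's disruptive insertion counts (vectorized).
#' @param H,L the population totals.
#' @return Numeric vector of two-sided P values in `[0, 1]`.
#' @examples
#' fisherExactP(3, 3, 0, 3)  # table [[3,0],[0,3]] -> 0.1
#' @export
fisherExactP <- function(a, H, b, L) {
  if (any(a < 0 | b < 0 | H - a < 0 | L - b < 0))
    stop("input error: negative counts")
  n <- max(length(a), length(H), length(b), length(L))
  a <- rep_len(a, n); H <- rep_len(H, n)
  b <- rep_len(b, n); L <- rep_len(L, n)
  vapply(seq_len(n), function(i) {
    k <- a[i] + b[i]
    x <- max(0, k - L[i]):min(H[i], k)
    lp <- dhyper(x, H[i], L[i], k, log = TRUE)
    obs <- dhyper(a[i], H[i], L[i], k, log = TRUE)
    min(1, sum(exp(lp[lp <= obs + log1p(1e-7)])))
  }, 0)
}

#' Per-gene enrichment testing of a sorted screen
#'
#' Computes the mutational index and two-sided Fisher's exact P value for
#' every gene in a counts table and calls regulators at `alpha`. This is
#' the per-gene row of a fishtail plot.
#'
#' @param counts a `DataFrame`/data.frame with columns `gene_id`, `a`, `b`,
#'   `H`, `L` as produced by [tabulateCounts()].
#' @param alpha significance level; the call is strict (`P < alpha`, so
#'   `P == alpha` is not significant).
#' @param fdr if `TRUE`, Benjamini-Hochberg adjusted P values are used for
#'   the significance call (raw P values are always reported). Off by
#'   default: screens of this design are traditionally read at raw
#'   `P < 0.05`.
#' @return A `DataFrame` with columns `gene_id`, `a`, `b`, `H`, `L`, `mi`,
#'   `log2_mi` (exact, may be infinite or NaN), `p_value`, `p_adjusted`
#'   (when `fdr`), `total_insertions`, `significant`, `direction`
#'   (`enriched_high` / `enriched_low` / `none`) and `regulator`.
#'   `metadata(.)` stamps `alpha` and the multiple-testing policy.
#' @seealso [callRegulators()], [fishtailTable()], [compareScreens()]
#' @export
testScreen <- function(counts, alpha = 0.05, fdr = FALSE) {
  res <- DataFrame(gene_id = counts$gene_id,
                   a = counts$a, b = counts$b,
                   H = counts$H, L = counts$L)
  res$mi <- mutationalIndex(res$a, res$H, res$b, res$L)
  res$log2_mi <- log2(res$mi)
  res$p_value <- fisherExactP(res$a, res$H, res$b, res$L)
  res$total_insertions <- res$a + res$b
  callRegulators(res, alpha = alpha, fdr = fdr)
}

#' Call significant regulators with direction
#'
#' Flags genes with `P < alpha` (strict inequality) and assigns the
#' enrichment direction from the mutational index. The phenotype-level
#' reading is emitted as a `regulator` column: a significant gene with
#' MI < 1 is a *positive regulator* of the sorted phenotype (its
#' disruptions are depleted from the high tail), and a significant gene
#' with MI > 1 is a *negative regulator* or suppressor (its disruptions
#' accumulate in the high tail — the behaviour of a gene whose loss raises
#' the signal).
#'
#' @param results a results table with `p_value` and `mi` columns.
#' @param alpha significance level (strict).
#' @param fdr use Benjamini-Hochberg adjusted P values for the call.
#' @return The table with `significant`, `direction` and `regulator`
#'   columns (re)computed and the policy stamped in `metadata(.)`.
#' @export
callRegulators <- function(results, alpha = 0.05, fdr = FALSE) {
  p <- results$p_value
  if (fdr) {
    results$p_adjusted <- stats::p.adjust(p, method = "BH")
    p <- results$p_adjusted
  }
  results$significant <- p < alpha
  results$direction <- rep("none", nrow(results))
  results$direction[results$significant & results$mi > 1] <- "enriched_high"
  results$direction[results$significant & results$mi < 1] <- "enriched_low"
  results$regulator <- c(none = "none",
                         enriched_high = "negative regulator",
                         enriched_low = "positive regulator"
                         )[results$direction]
  names(results$regulator) <- NULL
  metadata(results)$alpha <- alpha
  metadata(results)$multiple_testing <- if (fdr) "BH" else "none"
  results
}

#' Plot-ready fishtail table
#'
#' One point per gene: x = total disruptive insertions (`a + b`), y =
#' log2 mutational index, coloured by significance call. Genes with an
#' undefined MI (`a = b = 0`) are excluded. With `pseudocount = TRUE`
#' (default) a Haldane-style +0.5 on `a` and `b` makes zero-count genes
#' plottable at finite y; the policy is stamped in `metadata(.)`. Rows are
#' ordered by `gene_id` for deterministic output.
#'
#' @param results a results table from [testScreen()].
#' @param pseudocount apply the Haldane smoothing for the y coordinate.
#' @return A `DataFrame` with columns `gene_id`, `total_insertions`,
#'   `log2_mi`, `significant`, `direction`, `regulator`.
#' @export
fishtailTable <- function(results, pseudocount = TRUE) {
  keep <- !is.nan(results$mi)
  r <- results[keep, , drop = FALSE]
  y <- if (pseudocount) log2(.haldaneMI(r$a, r$H, r$b, r$L))
       else log2(r$mi)
  out <- DataFrame(gene_id = r$gene_id,
                   total_insertions = r$total_insertions,
                   log2_mi = y,
                   significant = r$significant,
                   direction = r$direction,
                   regulator = r$regulator)
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  metadata(out)$pseudocount <- if (pseudocount) "haldane+0.5" else "none"
  out
}

#' Fishtail plot of a sorted screen
#'
#' Scatter of per-gene log2 mutational index against total insertion
#' count on a log axis; significant positive regulators (enriched in the
#' low tail) are light blue and negative regulators (enriched in the high
#' tail) orange, the conventional colouring of such plots.
#'
#' @param results a results table from [testScreen()] (or a table from
#'   [fishtailTable()]).
#' @param pseudocount passed to [fishtailTable()] when `results` still
#'   carries raw counts.
#' @return A `ggplot` object.
#' @export
plotFishtail <- function(results, pseudocount = TRUE) {
  ft <- if (!is.null(results$a)) fishtailTable(results, pseudocount)
        else results
  df <- as.data.frame(ft)
  df$call <- factor(df$regulator,
                    levels = c("none", "positive regulator",
                               "negative regulator"))
  ggplot2::ggplot(df, ggplot2::aes(x = total_insertions, y = log2_mi,
                                   colour = call)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_colour_manual(values = c(
      "none" = "grey60",
      "positive regulator" = "#7fc3e8",
      "negative regulator" = "#f09243")) +
    ggplot2::labs(x = "insertions (high + low)",
                  y = expression(log[2] ~ "mutational index"),
                  colour = NULL) +
    ggplot2::theme_classic()
}

#' Compare the mutational indices of two screens
#'
#' For every gene of the shared universe, the difference in
#' log2-transformed mutational index between the two screens, restricted
#' to genes with at least `minInsertions` disruptive insertions in *each*
#' screen (the filter of a two-screen comparison plot; genes failing it
#' are carried with `passes_filter = FALSE` and no delta). Genes whose
#' exact MI is 0 or infinite in either screen get a finite delta only
#' under the Haldane `pseudocount`.
#'
#' @param results1,results2 results tables from [testScreen()] over the
#'   same gene universe.
#' @param minInsertions minimum `a + b` required in both screens
#'   (default 30).
#' @param pseudocount use Haldane-smoothed MIs for the log2 difference.
#' @return A `DataFrame` with columns `gene_id`, `log2_mi_screen1`,
#'   `log2_mi_screen2`, `delta_log2_mi`, `passes_filter`.
#' @export
compareScreens <- function(results1, results2, minInsertions = 30L,
                           pseudocount = FALSE) {
  shared <- intersect(results1$gene_id, results2$gene_id)
  if (!length(shared))
    stop("input error: disjoint gene universes")
  genes <- union(results1$gene_id, results2$gene_id)
  i1 <- match(genes, results1$gene_id)
  i2 <- match(genes, results2$gene_id)
  lmi <- function(r, i) {
    if (pseudocount) log2(.haldaneMI(r$a[i], r$H[i], r$b[i], r$L[i]))
    else log2(r$mi[i])
  }
  l1 <- lmi(results1, i1)
  l2 <- lmi(results2, i2)
  pass <- !is.na(i1) & !is.na(i2) &
    (results1$total_insertions[i1] >= minInsertions) &
    (results2$total_insertions[i2] >= minInsertions)
  pass[is.na(pass)] <- FALSE
  delta <- ifelse(pass, l1 - l2, NA_real_)
  delta[pass & !is.finite(delta)] <- NA_real_
  out <- DataFrame(gene_id = genes,
                   log2_mi_screen1 = l1,
                   log2_mi_screen2 = l2,
                   delta_log2_mi = delta,
                   passes_filter = pass)
  metadata(out)$min_insertions <- minInsertions
  metadata(out)$pseudocount <- if (pseudocount) "haldane+0.5" else "none"
  out
}
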