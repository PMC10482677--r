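#' Lipid class vocabulary
#'
#' The shotgun-lipidomics class labels accepted by the postprocessing
#' functions: glycerophospholipids and their lyso forms, sphingolipids,
#' neutral lipids, and ether-linked variants (prefixed `e`, e.g. `ePC`).
#'
#' @return Character vector of class labels.
#' @export
lipidClasses <- function() {
  base <- c("CE", "Cer", "CL", "DAG", "HexCer", "LPA", "LPC", "LPE",
            "LPG", "LPI", "LPS", "PA", "PC", "PE", "PG", "PI", "PS",
            "SM", "TAG")
  c(base, paste0("e", base))
}

#' Filter lipid identifications on signal-to-noise and blank intensity
#'
#' Retains a record iff its signal-to-noise ratio is strictly greater than
#' `snMin` AND its amount is strictly greater than `blankFold` times the
#' amount in the matched blank sample. Both inequalities are strict, so a
#' record at exactly S/N = 5 or exactly 5x blank is rejected. Idempotent.
#'
#' @param records a data.frame with columns `sample_id`, `species`,
#'   `lipid_class`, `amount`, `signal_to_noise`, `blank_amount`.
#' @param snMin signal-to-noise threshold (default 5).
#' @param blankFold blank-fold threshold (default 5).
#' @return The retained records, with a per-rule rejection report in
#'   `attr(., "filter_report")` (counts failing S/N only, blank only,
#'   both, and retained).
#' @examples
#' tab <- data.frame(sample_id = "s1", species = c("TAG 52:2", "PC 34:1"),
#'                   lipid_class = c("TAG", "PC"), amount = c(10, 10),
#'                   signal_to_noise = c(20, 5), blank_amount = c(1, 1))
#' filterIdentifications(tab)  # PC 34:1 rejected: S/N not > 5
#' @export
filterIdentifications <- function(records, snMin = 5, blankFold = 5) {
  need <- c("amount", "signal_to_noise", "blank_amount")
  if (!all(need %in% names(records)))
    stop("input error: records need columns ",
         paste(need, collapse = ", "))
  if (any(records$amount < 0))
    stop("input error: negative amounts")
  if (any(records$signal_to_noise < 0))
    stop("input error: negative signal-to-noise")
  okSN <- records$signal_to_noise > snMin
  okBlank <- records$amount > blankFold * records$blank_amount
  keep <- okSN & okBlank
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "filter_report") <- data.frame(
    n_input = nrow(records),
    n_fail_sn_only = sum(!okSN & okBlank),
    n_fail_blank_only = sum(okSN & !okBlank),
    n_fail_both = sum(!okSN & !okBlank),
    n_retained = sum(keep))
  out
}

#' Fractional molar abundances (mol\%)
#'
#' Per sample, each lipid species' amount (or each class' summed amount) as
#' a percentage of the sample's total over all retained species — apply
#' [filterIdentifications()] first; the denominator is the post-filter set.
#' Per-sample totals sum to 100 (within 1e-9). A sample with zero total is
#' flagged with a warning and `NA` mol\%.
#'
#' @param records a (filtered) data.frame with `sample_id`, `species`,
#'   `lipid_class`, `amount`.
#' @param by `"species"` (default) or `"class"`.
#' @return A data.frame of `sample_id`, `species` (+ `lipid_class`) or
#'   `lipid_class`, `amount`, `mol_percent`.
#' @examples
#' tab <- data.frame(sample_id = "s1",
#'                   species = paste("PC", 1:4), lipid_class = "PC",
#'                   amount = c(1, 2, 3, 4))
#' molPercent(tab)$mol_percent  # 10 20 30 40
#' @export
molPercent <- function(records, by = c("species", "class")) {
  by <- match.arg(by)
  if (by == "class") {
    amt <- tapply(records$amount,
                  list(records$sample_id, records$lipid_class), sum)
    out <- data.frame(
      sample_id = rep(rownames(amt), ncol(amt)),
      lipid_class = rep(colnames(amt), each = nrow(amt)),
      amount = as.numeric(amt), stringsAsFactors = FALSE)
    out <- out[!is.na(out$amount), , drop = FALSE]
  } else {
    out <- data.frame(sample_id = records$sample_id,
                      species = records$species,
                      lipid_class = records$lipid_class,
                      amount = records$amount,
                      stringsAsFactors = FALSE)
  }
  total <- tapply(out$amount, out$sample_id, sum)
  tot <- total[out$sample_id]
  if (any(total == 0)) {
    warning("zero total amount in sample(s): ",
            paste(names(total)[total == 0], collapse = ", "),
            "; mol% undefined there")
    tot[tot == 0] <- NA_real_
  }
  out$mol_percent <- 100 * out$amount / as.numeric(tot)
  out <- out[order(out$sample_id,
                   if (by == "class") out$lipid_class else out$species), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Contrast lipid mol\% tables between two conditions
#'
#' Per-species difference and log2 ratio of mol\% between condition A and
#' condition B (species-level tables from [molPercent()], averaged over
#' each condition's samples first). Species present in only one condition
#' are carried with a `status` marker and excluded from ratios unless the
#' Haldane-style `pseudocount` is applied to both mol\% values. The
#' contrast is antisymmetric: swapping A and B negates both the difference
#' and the log2 ratio.
#'
#' @param tableA,tableB species-level mol\% data.frames (columns `species`,
#'   `lipid_class`, `mol_percent`; multiple samples are averaged).
#' @param pseudocount numeric added to both mol\% values before the log2
#'   ratio (0 = exact, zero/absent species get `NA` ratios).
#' @return A data.frame with `species`, `lipid_class`, `mol_percent_A`,
#'   `mol_percent_B`, `mean_mol_percent` (for point sizing),
#'   `delta_mol_percent` (A - B), `log2_ratio` and `status`
#'   (`shared` / `absent_in_A` / `absent_in_B`).
#' @export
contrastConditions <- function(tableA, tableB, pseudocount = 0) {
  avg <- function(tab) {
    m <- tapply(tab$mol_percent, tab$species, mean)
    cls <- tab$lipid_class[match(names(m), tab$species)]
    data.frame(species = names(m), lipid_class = cls,
               mol_percent = as.numeric(m), stringsAsFactors = FALSE)
  }
  A <- avg(tableA); B <- avg(tableB)
  if (!length(intersect(A$species, B$species)))
    stop("input error: no shared species between conditions")
  species <- sort(union(A$species, B$species))
  ia <- match(species, A$species); ib <- match(species, B$species)
  ma <- A$mol_percent[ia]; mb <- B$mol_percent[ib]
  status <- ifelse(is.na(ia), "absent_in_A",
                   ifelse(is.na(ib), "absent_in_B", "shared"))
  cls <- ifelse(is.na(ia), B$lipid_class[ib], A$lipid_class[ia])
  delta <- ifelse(status == "shared", ma - mb, NA_real_)
  la <- ma; lb <- mb
  if (pseudocount > 0) {
    la[is.na(la)] <- 0; lb[is.na(lb)] <- 0
    ratio <- log2((la + pseudocount) / (lb + pseudocount))
  } else {
    ratio <- ifelse(status == "shared" & ma > 0 & mb > 0,
                    log2(ma / mb), NA_real_)
  }
  out <- data.frame(species = species, lipid_class = cls,
                    mol_percent_A = ma, mol_percent_B = mb,
                    mean_mol_percent = rowMeans(cbind(ma, mb),
                                                na.rm = TRUE),
                    delta_mol_percent = delta,
                    log2_ratio = ratio,
                    status = status, stringsAsFactors = FALSE)
  attr(out, "pseudocount") <- pseudocount
  out
}
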