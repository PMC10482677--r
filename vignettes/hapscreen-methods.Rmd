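---
title: "Statistical methods of the hapscreen package"
author: "hapscreen authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods of the hapscreen package}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hapscreen)
```

## The screen model

A haploid gene-trap screen mutagenizes a pool of haploid cells so that
each cell carries (ideally) a single insertional cassette, stains the pool
for a quantitative phenotype, and FACS-sorts the extreme tails of the
fluorescence distribution — conventionally the lowest and highest 5%.
Insertion sites recovered from each tail by junction-read sequencing are
the data. A gene is *disrupted* by an insertion only when the cassette is
integrated in the sense orientation (cassette strand equal to the gene's
transcriptional strand) within the gene body's 5'UTR, exons or introns;
the 3'UTR is excluded because a splice-acceptor trap landing downstream of
the coding sequence does not truncate the protein, and antisense
integrations leave splicing intact. `classifySites()` implements exactly
this rule; 3'UTR and antisense hits are retained in the annotation output
for diagnostics but never enter any count.

### The mutational index

For gene $g$, let $a$ and $b$ be its unique disruptive insertion counts in
the high and low populations, and $H$, $L$ the totals of unique disruptive
insertions in each population. The mutational index is the leave-one-out
odds ratio

$$\mathrm{MI}_g = \frac{a/(H-a)}{b/(L-b)},$$

i.e. each gene's count normalized by the total of the *other* disruptive
mutations in its population. `mutationalIndex()` keeps zero counts exact:
$a=0$ gives MI $=0$, $b=0<a$ gives $+\infty$, and $a=b=0$ is undefined
(NaN, excluded from plots). Significant genes with MI $>1$ are reported as
negative regulators (suppressors — their disruptions accumulate in the
high tail, the behaviour of a gene whose loss raises the signal); MI $<1$
marks positive regulators.

### The exact test

Each gene's 2×2 table $[[a, H-a], [b, L-b]]$ — the same table whose odds
ratio is the MI — is tested with a two-sided Fisher's exact test.
Sidedness follows the minimum-likelihood convention: the P value is the
sum of hypergeometric probabilities of all tables with the observed
margins whose probability does not exceed that of the observed table. The
inclusion comparison uses a relative tolerance of $10^{-7}$ and is carried
out in log space (via `dhyper(log = TRUE)`), which keeps the enumeration
stable for totals in the thousands. Calls are strict: $P < \alpha$, so a
gene at exactly $P = 0.05$ is not significant. No multiple-testing
correction is applied by default, matching the conventional raw
$P < 0.05$ reading of such screens; Benjamini–Hochberg adjustment is
available via `testScreen(fdr = TRUE)`.

### Zero counts and the pseudocount policy

The MI itself is never smoothed. For log-scale displays
(`fishtailTable()`) and screen comparisons (`compareScreens()`), where
$\log_2 0$ and $\log_2 \infty$ are unusable, an optional Haldane-style
correction adds $0.5$ to $a$ and $b$ only (the totals are left untouched):

$$\mathrm{MI}^{(h)} = \frac{(a+0.5)/(H-a)}{(b+0.5)/(L-b)}.$$

The policy in force is stamped into the `metadata()` of every table that
used it. `compareScreens()` defaults to the exact MI (genes with
zero-count MIs then get `NA` deltas); the comparison is restricted to
genes with at least 30 disruptive insertions in *each* screen, the
customary filter for cross-screen MI differences, and we read
"insertions" as disruptive insertions ($a+b$).

## The synthetic screen generator

`buildToyGenome()` and `simulateSortedScreen()` generate the study
conditions the statistics are validated under, scaled to desk size:

| parameter | default | meaning |
|---|---|---|
| `nGenes` | 50 | genes packed disjointly on one chromosome |
| `genomeLength` | 150 kb | single chromosome, uniform random A/C/G/T |
| `geneLengthRange` | 1500–3000 bp | gene bodies: 5'UTR (10%), 2–4 exons with introns, 3'UTR (15%) |
| `nCells` | 200,000 | mutagenized cells, one insertion each |
| `tailFraction` | 0.05 | the sorted 5% tails |
| `cellsSortedPerTail` | 8,000 | cells recovered per tail |
| `phenotypeNoiseSd` | 1 | Gaussian phenotype noise (fluorescence units) |
| `orientationProbSense` | 0.5 | in-gene sense probability |
| `readLength` | 50 bp | junction reads |
| `mismatchRate` | (0.9, 0.1, 0) | P(0/1/2 substitutions per read) |

A real screen sorts $10^7$ cells per tail from $10^9$ mutagenized cells;
we keep the *ratios* (5% tails, recovery of most sorted cells) and shrink
the absolute scale 1000-fold so a full calibration of 2,000 null
gene-replicates runs in about a minute. At these defaults each gene
collects roughly 50 disruptive insertions per tail, deep enough that the
exact test's discreteness does not dominate its operating
characteristics.

The phenotype model is Gaussian-additive: every cell's phenotype is
$\mathcal{N}(0, \sigma^2)$ noise plus the configured effect of the gene
its insertion disrupts (using the same classification rule as the
analysis). Cells are ranked, the top and bottom `tailFraction` form the
pools, and `cellsSortedPerTail` cells are drawn without replacement from
each; recovered insertions are de-duplicated to unique sites, mirroring
unique-site (not read-depth) counting. One insertion per cell keeps the
ground truth unambiguous — multi-insertion cells, insertion hotspots,
chromatin bias, PCR chimeras and growth selection are deliberately not
modelled, so passing calibration here demonstrates the correctness of the
statistics under the model's assumptions, not robustness to those
artefacts in real data.

What the generator *does* reproduce, and the tests verify end to end:

* **Null calibration** — with all gene effects zero, the fraction of
  genes called at $\alpha = 0.05$ over 2,000 gene-replicates lies within
  the 95% binomial interval around 0.05. The exact test is mildly
  conservative at finite counts, so the empirical rate sits slightly
  below nominal (typically 4–5% at this count depth); at shallower
  coverage the conservatism grows.
* **Effect recovery** — a gene shifted by 8 phenotype SDs essentially
  relocates all its disrupted cells into one tail; with $\geq 30$
  recovered insertions it is called significantly and in the correct
  direction in far more than 90% of replicates, and a positive-shift
  (suppressor-like) gene is always `enriched_high` / negative regulator.

## Read mapping

`mapRead()` implements the one-mismatch contract: a placement is valid if
the Hamming distance (substitutions only, `N` never matches) is at most
`maxMismatches` (default 1) on either strand of any chromosome; the
unique best placement wins, ties at the minimal distance are discarded as
ambiguous (deterministic and conservative, rather than random
assignment), and reads two substitutions away from their only source
locus are unmapped. Indels are not tolerated — junction reads are short
and the contract is mismatch-tolerant exact matching — and the read's 5'
end defines the insertion coordinate. The scan itself uses
`Biostrings::matchPattern()`; the contract, not the search strategy, is
what the tests pin down (an exhaustive naive Hamming scan over a 100 kb
genome serves as the oracle, and a strand-symmetry property guards the
coordinate arithmetic).

## Bookkeeping conventions

Coordinates are 1-based closed `GRanges` internally; BED output is
0-based half-open (via rtracklayer) and the simplified TSV annotation is
written 0-based half-open and converted on read. Both gene-body ends
behave as half-open boundaries in those external formats, and tests pin
the first and last base of a gene body.

With overlapping gene models, a site disruptive for $k$ genes counts once
per gene in the per-gene tallies but only once in the totals $H$ and $L$,
so the MI normalizer is never double-inflated; with disjoint models (as
generated) $\sum_g a_g = H$ exactly, a conservation identity the suite
asserts. Totals contain disruptive sites only.

## Calorimetry and lipidomics modules

The calorimetry functions apply the substrate-oxidation closed forms as
printed, treating units as opaque labels carried from the input: RER
$= V_{CO_2}/V_{O_2}$, glucose oxidation
$((4.585 V_{CO_2}) - (3.226 V_{O_2}))\times 4$, fat oxidation
$((1.695 V_{O_2}) - (1.701 V_{CO_2}))\times 9$, each divisible by lean
mass. Negative oxidation rates are reported and counted, never clipped —
clipping would bias fed/fasted phase means. Phase labels come from an
explicit column, not from food-intake inference.

The lipidomics postprocessing starts from an identified, internal-
standard-scaled intensity table (spectral interpretation is out of
scope). Identification filters are strict inequalities — S/N $> 5$ and
amount $> 5\times$ the matched blank — so records at either boundary are
rejected; the filter is idempotent and reports per-rule rejection counts.
mol% is computed over the species that survive filtering (the denominator
is the post-filter set, configurable by recomputing on any subset), sums
to 100 per sample within $10^{-9}$, and condition contrasts
(per-species Δmol% and log2 ratio) are antisymmetric under swapping the
conditions, with species absent from one condition marked and excluded
from ratios unless a pseudocount is requested.

## Numerical and design choices

* All stochastic operations require an explicit seed
  (`SortedScreenConfig@seed`); per-stage streams are derived offsets so a
  genome, its screen and its reads are independently reproducible, and
  RNG state is restored afterwards (`withr::with_seed`).
* Site ordering is fully deterministic (chromosome, position, then
  strand), making `collapseSites()` idempotent and order-independent.
* The Fisher enumeration is $O(\text{support})$ per gene with
  vectorized `dhyper`; 50 genes at totals of a few thousand test in
  milliseconds.
* Degenerate inputs fail loudly: tails of size zero, gene layouts that
  cannot fit the genome, counts with $a > H$, malformed BED lines (with
  the offending line number), zero-total lipid samples (warning + NA).
* Problem sizes used by the validation suite — 2,000 null
  gene-replicates, 100 effect-recovery replicates, a 100 kb mapper-oracle
  genome with 120 reads — were chosen as the smallest sizes at which the
  binomial calibration interval and the recovery bound are statistically
  meaningful.

## Known limitations

The generator's simplifications (above) bound what green tests prove
about real screens. The mapper is exhaustive rather than indexed, which
is appropriate for toy genomes up to a few hundred kb; a real-genome run
would swap in an indexed matcher behind the same unique-best-placement
contract. Fed/fasted regression modelling of energy expenditure and raw
MS identification are out of scope by design.
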