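---
title: "Identifying eRNAs and building coordination networks with ernanet"
author: "ernanet authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying eRNAs and building coordination networks with ernanet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ernanet)
```

## The procedure

Enhancer RNAs (eRNAs) are long noncoding transcripts produced from active
enhancer elements; superenhancer lncRNAs (SE-lncRNAs) are lncRNAs arising
from large enhancer clusters. Neither class carries a sequence signature, so
both are identified *positionally*: a lncRNA annotation that shares at least
one nucleotide with an enhancer (or superenhancer) interval is called an
eRNA (or SE-lncRNA). `ernanet` implements this identification and the
downstream regulatory analysis as one chain:

1. **Catalogue assembly** (`merge_catalogs`). Enhancers come from three
   kinds of evidence — database-predicted DHS enhancers (`DENDB`), histone
   mark/DNase-supported enhancers (`ENCODE`), and reporter-assay enhancers
   (`STARR`). Redundancy removal collapses *coordinate-identical* records
   and unions their source tags; overlapping-but-distinct intervals are kept
   separate, because merging them would change every downstream overlap
   result in ways the per-source accounting could not track.
2. **Activity annotation** (`classify_active`). An enhancer is *active*
   when it lies in open chromatin and its H3K27ac max-Z is high; if it is
   TSS-proximal (nearest TSS at most 2 kb away) it must additionally have a
   low H3K4me3 max-Z, which separates enhancers from promoter signatures.
3. **Calling** (`call_ernas`, `call_se_lncrnas`). The one-nucleotide
   overlap rule, applied per probe with deduplication: one call per probe,
   sources unioned over all overlapping enhancers.
4. **Differential expression** (`differential_expression`). On quantile-
   normalised log2 signals, per probe: linear fold change
   $2^{|\bar{x}_T - \bar{x}_N|}$ (a magnitude, with direction reported
   separately) and a two-sided pooled-variance Student's *t* test. A probe
   is significant iff fold change $\ge 2$ and raw $p < 0.05$.
5. **Target assignment** (`assign_targets`, `integrate_with_de_mrna`).
   Candidate targets of a differentially expressed eRNA are genes within a
   300 kb window (nearest gene by default); candidates are kept only when
   the gene itself is differentially expressed, and a pair is *concordant*
   when eRNA and gene move in the same direction.
6. **Enrichment** (`overrepresentation_test`). Hypergeometric
   over-representation of the target genes against user-supplied GMT
   collections, with fold enrichment $(k/n)/(K/N)$.
7. **Coordination network** (`build_coordinations`, `ctcf_mediated`). A
   *coordination* is a quadruple (enhancer, eRNA, TF, target gene) in which
   the enhancer and the target's 2 kb upstream promoter share a TF motif
   hit and are linked by a chromatin-interaction anchor pair (3C/4C/5C/
   ChIA-PET). A coordination is CTCF-mediated when CTCF peaks occupy both
   loop ends. A node's degree is the number of coordinations it appears in.

## Tunable parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `fc_threshold` | 2 | linear ratio | DE fold-change filter |
| `p_threshold` | 0.05 | probability | raw-p filter (DE and enrichment) |
| `window` | 300 000 | nt | target-gene search window (inclusive) |
| `promoter_length` | 2 000 | nt | strand-aware upstream promoter |
| `tss_proximal` | 2 000 | nt | TSS-proximity bound (inclusive) |
| `min_overlap` | 1 | nt | calling overlap rule |
| `z_high`, `z_low` | 1.64 | z-score | "high" H3K27ac / "low" H3K4me3 |
| `pseudocount` | 1 | intensity | added before log2 |

The first six are the workflow's published values. The max-Z cutoffs are
*not*: the source material calls them only "high" and "low", so the package
defaults to 1.64 — the one-sided 5% normal quantile, the conventional
reading of a z-score threshold — and exposes both as configuration.

## Design choices where the design was open

* **Unpaired pooled-variance *t* by default.** The samples are paired
  tumour/adjacent-normal tissue, but the stated test is the plain
  two-group Student's *t*; the literal reading is the classic
  pooled-variance unpaired test. A `paired = TRUE` mode is provided, and on
  data with strong per-patient baselines it is considerably more powerful.
* **Nearest-gene versus all-genes-in-window.** "Genes within 300 kb" and a
  nearest-feature tool disagree when several genes fall in the window; both
  modes exist (`mode = "nearest"` / `"all"`), nearest is the default, and
  ties at the minimal distance are all reported. The window bound is read
  as inclusive (a gene at exactly 300 kb qualifies).
* **Distances are interval-to-interval**, not to the TSS, matching
  nearest-feature semantics of BED tooling; overlap distance is 0 and the
  gap between book-ended features is 0. All coordinates are 0-based
  half-open BED throughout; strand is ignored by overlap and distance.
* **Degree = coordination incidence**, not distinct-neighbour count. This
  convention makes a printed per-enhancer coordination table directly
  reproducible: an enhancer appearing in 25 rows has degree 25.
* **Fold change from log2 group means** (ratio of geometric means), the
  standard for log-scale microarray signals. On the linear-scale validation
  platform the fold change is the ratio of arithmetic group means and the
  test is a two-sided Mann-Whitney, matching RPKM-like data.
* **No multiplicity correction by default.** The workflow filters on raw
  p-values; this inflates the family-wise error rate and is retained only
  for fidelity. `overrepresentation_test(adjust = TRUE)` applies
  Benjamini-Hochberg for users who want it.
* **An eRNA's chromatin state** is inherited from overlapping
  reporter-assay (STARR) enhancers only — open if any is open, closed if
  all are closed, unknown otherwise — since those are the enhancers whose
  open/closed status is meaningful independently of chromatin data.

## Numerical and degenerate-input conventions

* Quantile normalisation (via `limma::normalizeQuantiles`) leaves every
  column with the identical sorted vector; negative intensities are an
  error, constant matrices pass through unchanged.
* A probe with equal group means gets fold change 1, direction "up" by
  convention, and can never be significant; a probe constant in both groups
  gets $p = 1$ when means agree (no evidence) and $p = 0$ otherwise
  (infinite *t*).
* Mann-Whitney p-values on fully tied vectors are defined as 1.
* Enrichment results are sorted by p then set id; sets empty after
  intersection with the universe are skipped with a warning; `k = 0` gives
  fold 0 and $p = 1$.
* Promoters truncate at position 0 and never become empty; a TSS inside an
  enhancer gives proximity distance 0.
* Deterministic output orderings everywhere (coordinate order for
  catalogues, id order for calls and coordinations), so byte-identical
  reruns are an invariant, not an accident.

## What the synthetic generator emulates — and what it does not

`generate_study()` writes a complete toy study: a two-chromosome genome
with genes on a fixed grid, per-source enhancer catalogues with controlled
cross-source duplication, superenhancers, open-chromatin regions, a paired
tumour/normal expression matrix, motif hits, interaction anchors, CTCF
peaks, GMT gene sets, and a `ground_truth.json` naming every planted
structure. Expression is log-normal: per-probe baseline
$\mathcal{N}(6, 1)$ on the log2 scale, per-sample noise
$\mathcal{N}(0, 0.3)$, and planted probes shifted by $\pm 2$ log2 units in
tumours — microarray-like scales with three sample pairs, mirroring the
motivating study's design. Defaults plant 500 eRNAs (400/50/50 by source),
100 SE-lncRNAs, 120 eRNA-target pairs (20 discordant), 50 coordinations
(20 CTCF-mediated), and decoys against every rule: book-ended probes with
zero overlap, DE eRNAs in a gene desert beyond the 300 kb window,
motif-sharing pairs without anchors, anchored pairs without shared motifs,
and enhancer-only CTCF peaks.

The genomic layout is deliberately deterministic — only expression values
are drawn from the seeded RNG — so the interval rules recover the planted
truth *exactly*, and the tests assert exact recovery. That is a statement
about the rules, not about real data: real annotations have overlapping
genes, nested transcripts, ambiguous nearest genes, probe
cross-hybridisation, batch structure and tumour purity effects, none of
which the generator models. Passing the recovery suite shows the
implementation applies its stated rules correctly; it does not show the
rules are biologically sufficient. The statistical claims that *are*
transferable — type-I control of the raw-p filter near 5% under the null
and high recall for 2-log2-unit effects at $\sigma = 0.3$ with three pairs
— are tested by simulation under exactly those conditions.

One interaction worth knowing: running the optional normalisation path
(`run_study(..., normalize = TRUE)`) on a *small* bundle compresses the
largest planted shifts, because quantile normalisation pools column tails
across few probes. At the default scale (5 000 probes) this is negligible;
at toy scale (hundreds of probes) recovery through that path is high but
not exact, and the tests encode that expectation.

## Problem sizes in the test-suite

The per-module tests run on a down-scaled study (80 genes, 200 lncRNA
probes, 72 enhancers) and the acceptance-level checks on the default study
(1 000 genes, 5 000 probes, 785 catalogue records); oracle comparisons use
random collections up to 200×200 intervals, 100 random probes for the
*t*-test, and exhaustive enumeration for hypergeometric universes up to
N = 30; calibration uses 500 planted and 4 500 null probes. These sizes
were chosen so the whole suite exercises every rule at full fidelity while
completing in about a minute.

## Known limitations

* Motif discovery is out of scope: the network stage consumes motif-hit
  tables (TF × region), however produced; only the synthetic fixtures use
  the built-in exact-consensus scanner (`scan_consensus`).
* "CTCF enrichment" is operationalised as peak overlap — peak calls, not
  signal, are the representation this package accepts.
* Raw-p filtering and the unpaired default are fidelity choices, not
  statistical recommendations (see above).
* Per-source eRNA counts are call-level annotations; the package does not
  model the upstream peak calling, max-Z computation or reporter-assay
  processing that produced the catalogues.

## A worked run

```{r, eval = FALSE}
library(ernanet)
dir <- tempfile("study")
bundle <- generate_study(simulation_config(seed = 42), dir)
res <- run_study(dir)
print(res)
summary(res)

# every planted coordination is recovered
setequal(
  do.call(paste, res$coordinations[, 1:4]),
  do.call(paste, bundle$ground_truth$coordinations[, 1:4])
)
```
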