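# ernanet

Identification of enhancer RNAs (eRNAs) and superenhancer lncRNAs
(SE-lncRNAs) from interval overlap, paired tumour/normal differential
expression, target-gene assignment, gene-set enrichment, and construction
of an eRNA–(enhancer)–TF–target coordination network with CTCF-mediation
annotation — the computational backbone of enhancer-transcript profiling
studies (the motivating use case is prostate-cancer microarray data), built
for analysts who have enhancer catalogues, a probe-level expression matrix
and regulatory evidence tables, and want the pipeline reproducible and
testable end to end.

## The method

eRNAs carry no sequence signature, so identification is positional: a
lncRNA annotation overlapping an enhancer interval by **≥ 1 nt** is an
eRNA; overlapping a superenhancer, an SE-lncRNA. Enhancers come from three
sources (database-predicted DHS, histone/DNase evidence, reporter assay),
deduplicated at identical coordinates with source tags unioned. An
enhancer is *active* iff it is in open chromatin with high H3K27ac max-Z
and, when TSS-proximal (≤ 2 kb), low H3K4me3 max-Z.

Differential expression on quantile-normalised log2 signals uses, per
probe,

> FC = 2^|x̄_T − x̄_N|,  two-sided pooled-variance Student's *t*,

with significance iff FC ≥ 2 and raw p < 0.05. Targets of DE eRNAs are the
nearest genes within ±300 kb that are themselves DE; a pair is
*concordant* when both move in the same direction. Target genes are tested
for over-representation against GMT gene sets with the hypergeometric
upper tail, fold enrichment (k/n)/(K/N). A **coordination** is a quadruple
(enhancer, eRNA, TF, target gene) whose enhancer and 2 kb target promoter
share a TF motif hit *and* are linked by a chromatin-interaction anchor
pair; it is *CTCF-mediated* when CTCF peaks occupy both loop ends. Node
degree is coordination incidence.

A seeded synthetic-study generator (`generate_study`) plants all of these
structures — plus decoys against every rule — and writes a ground-truth
record, so the full pipeline is testable without any external downloads.

## Worked example

```r
library(ernanet)
dir <- tempfile("study")
bundle <- generate_study(simulation_config(seed = 42), dir)
res <- run_study(dir)
print(res)
```

```
eRNA regulatory-network study
  enhancer catalogue: 785 records (400 active)
  eRNAs called: 505 (DENDB 405 / ENCODE 50 / STARR 50)
  SE-lncRNAs called: 100
  differentially expressed: 275 probes (125 eRNAs, 30 SE-lncRNAs)
  eRNA-target pairs (gene DE): 120; concordant eRNAs 83.3%
  coordinations: 50 (20 CTCF-mediated)
```

Reading the numbers: the merged catalogue holds 785 enhancers after
coordinate-level deduplication of the three sources, of which 400 pass the
active-enhancer rule. 505 lncRNA probes overlap an enhancer by at least one
nucleotide (the per-source split counts each call toward every source
supporting it); 100 overlap a superenhancer. The DE filter (FC ≥ 2, raw
p < 0.05) keeps 275 probes; 120 DE eRNAs have a DE nearest gene within
300 kb, 83.3% of them moving concordantly — in this bundle, exactly the
planted fraction (100 of 120 pairs were planted concordant; five planted
eRNAs sit in a gene desert and are reported unassigned). Motif sharing plus
interaction anchors yield the 50 planted coordinations, 20 of them with
CTCF at both loop ends:

```r
head(res$enrichment, 1)
#>            set_id  k   n   K    N      p_value fold_enrichment significant
#> 1 PLANTED_TARGETS 60 120 100 1000 4.758329e-36               5        TRUE
```

`export_network(res$coordinations, "network.sif", "sif")` writes a SIF
edge list plus a node-attribute table for Cytoscape-style viewers; a
GraphML export is also available. The same pipeline runs from the shell:

```sh
Rscript inst/cli/ernanet.R simulate --outdir study --seed 42
Rscript inst/cli/ernanet.R run-all study --outdir results
```

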