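---
title: "Methods: miCLIP m6A quantification and multi-omic integration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: miCLIP m6A quantification and multi-omic integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(m6apipe)
```

## Overview

`m6apipe` implements a transcript-centric analysis chain for
N6-methyladenosine (m6A) epitranscriptomics built around miCLIP
(m6A individual-nucleotide-resolution crosslinking and
immunoprecipitation):

1. **Site calling** from per-position miCLIP/input pileups via
   crosslink-induced mutation signatures (CIMS-style) with DRACH motif
   filtering.
2. **Quantification** of per-site m6A abundance as *normalized-to-input
   uTPM* (unique tags per million in a 21-nt window around the site,
   expressed relative to the matched input library) and of per-transcript
   abundance as *SN-uTPM* (the sum of site values), per region (5' UTR,
   CDS, 3' UTR) and per nucleotide.
3. **Translation-efficiency (TE) integration**: quintile binning by an m6A
   metric, ECDF comparison of the top vs bottom quintile's TE, Wilcoxon
   rank-sum testing, hypergeometric overlap enrichment of the top-20%
   m6A ∩ top-20% TE gene set, and preranked GSEA.
4. **Single-cell integration**: filtering and normalization of
   two-condition (control vs conditional-knockout of the m6A writer) count
   matrices, marker-based classification into four skin-epithelial
   populations (basal and suprabasal epidermis, WNT-high and WNT-low hair
   follicle), per-population expression-change Z scores with ±1.96
   classification, and the join of those Z scores against coding-sequence
   m6A density ("blue dots" = down-regulated & top-20% modified, "red
   dots" = up-regulated & top-20% modified), with gene-set enrichment and a
   Pearson chi-square test of condition × population occupancy.

Every stage is exercised end to end on a synthetic-data generator that
emulates the statistical structure of such a study, so the whole pipeline
is testable without any external data.

## The site-calling model

A miCLIP library records antibody-crosslink signatures as elevated
mutation fractions near methylated adenosines. The caller scans miCLIP
pileups per replicate and keeps a position as a candidate crosslink
signature when:

* unique-tag coverage ≥ `min_coverage` (default 10);
* the mutation fraction lies in `[r_lo, r_hi]` (default `[0.02, 0.5]`) —
  the lower bound excludes sequencing noise, the upper bound excludes
  genetic variants, which mutate every read;
* a one-sided binomial test of the mutation count against the background
  per-tag mutation rate (default 0.001) rejects at `alpha` (default 0.01)
  after Benjamini–Hochberg adjustment across candidate positions within
  the replicate.

The methylated adenosine is inferred at `position − crosslink_offset`
(default +1 nt, the conventional C→T signature position 3' of the
methylated A). The site is kept only if that base is an A whose 5-mer
context matches DRACH (D = A/G/U, R = A/G, then A, C, H = A/C/U; 18 of
the 1024 possible 5-mers) and it is detected in at least
`min_replicates_detected` replicates (default 2). These thresholds follow
common CLIP practice and are all exposed in `site_call_params()`.

## Quantification

**Window uTPM.** For each site, unique (deduplicated) tags overlapping the
21-nt window centred on the site are counted once and scaled by the
library's total unique tags: `uTPM = tags × 10^6 / library_total`.
Windows are clipped at transcript ends (no mirroring, which would invent
signal). Tags are represented as point events at their recorded position;
under that representation, per-window unique-tag counting and per-position
summation coincide, and the test suite checks the window count against a
brute-force per-tag scan.

**Normalized-to-input uTPM.** The ratio of the miCLIP window uTPM to the
matched input window uTPM, computed per replicate and averaged across
replicates. Sites whose input uTPM is zero are unquantifiable (the ratio
is undefined) and are excluded with a warning; a pseudocount `eps` is
available for users who prefer to retain them.

**SN-uTPM.** Per transcript, the sum of mean normalized-to-input uTPM over
its sites — full-length and per region, with per-nucleotide densities
(sum divided by region length). Region sums always add up to the
full-length sum for coding transcripts; non-coding transcripts get
full-length scores only, since the region partition presumes an mRNA. The
coding-sequence density (`density_cds`, "coding sequence SN-uTPM per nt")
is the default metric for all downstream integration, as CDS methylation
carries the translation-efficiency signal.

**Metagene profile.** Site positions are mapped to a normalized coordinate
`u ∈ [0,3)`: `u = tpos/utr5_len` in the 5' UTR, `1 + (tpos −
cds_start)/cds_len` in the CDS, `2 + (tpos − cds_end)/utr3_len` in the
3' UTR, so the start codon sits at `u = 1` and the stop-codon boundary at
`u = 2`. A histogram over `3 × n_bins` bins (default 20 per segment) is
normalized to sum 1. Sites on a zero-length UTR are assigned to the
adjacent segment boundary and counted once.

## Coordinates and annotation

Internal coordinates are 0-based half-open throughout; GTF input/output
uses the standard 1-based closed convention. CDS boundaries are stored in
transcript coordinates, derived once from genomic CDS features, with the
stop codon occupying `cds_end − 3 .. cds_end`. The pipeline assumes one
representative transcript model per gene; how multi-isoform genes are
collapsed is left to the caller, because no single collapsing policy is
canonical and all downstream scoring is gene-keyed.

## Translation-efficiency integration

Genes are sorted descending by the chosen m6A metric (ties broken by gene
id — a stable, deterministic rule) and split into five bins whose sizes
differ by at most one; quintile 5 is the top 20%. The TE of quintile 5 is
compared with quintile 1 by ECDF and a Wilcoxon rank-sum test. The
Wilcoxon implementation is exact (full enumeration of rank assignments)
for `n_a + n_b ≤ 12` without ties and otherwise uses the normal
approximation with tie and continuity corrections; it agrees with
`wilcox.test` wherever the two overlap and is calibrated under the null.

Overlap enrichment of a selection (e.g. top-20% m6A ∩ top-20% TE) against
gene-set collections uses the one-sided hypergeometric tail with BH FDR
across sets. This is a deliberate simplification of length-bias-weighted
approaches: the length-bias correction needs per-gene read counts that
this pipeline does not carry.

Preranked GSEA is the classical running-sum statistic: hits weighted by
`|metric|^exponent` normalized to one, misses decremented by `1/(N −
N_hits)`, enrichment score = signed maximum deviation, significance by
gene-label permutation with the estimator floor `1/(n_perm + 1)`. The
implementation is cross-checked in the tests against
`fgsea::calcGseaStat` but does not depend on it; the permutation null
replaces adaptive multilevel p-value schemes, which are unnecessary at
the problem sizes this package targets.

## Single-cell integration

Filtering removes cells first (fewer than `min_genes_per_cell` detected
genes; a cell at exactly the threshold is kept), then genes (expressed in
fewer than `min_cells_per_gene` remaining cells) — one pass each, in that
order. Conventional droplet thresholds are 1800 and 10; defaults in the
pipeline configuration are scaled to the synthetic transcriptome's size.

Normalization is per cell: `log10(1 + count × scale / cell_total)` with
`scale = 10^4` (the per-cell normalization scale is a convention; the
common 10,000 factor is used). The transform preserves sparsity and is
invariant to per-cell scaling of raw counts.

Cells are classified by marker panels: each marker's normalized
expression is z-scored across cells, a cell's population score is the
mean z over the panel, and the label is the argmax. Ties and non-positive
best scores yield "unassigned". This deterministic marker-argmax rule
replaces graph clustering: it is reproducible, directly testable against
simulated labels, and mirrors marker-based identity assignment.

Per-population expression change between conditions is summarized as a
Welch-type Z on normalized expression:
`z = (mean_cKO − mean_Ctrl)/sqrt(s²_cKO/n_cKO + s²_Ctrl/n_Ctrl)`, with
two-sided normal p-values, BH FDR within the population, and
classification *down* (`z < −1.96`) / *up* (`z > 1.96`) / *ns* (strict
inequalities, matching the conventional ±1.96 two-sided 5% bounds). A
hurdle-model alternative would model dropout explicitly; the Z statistic
is used here because it is the interchange quantity the downstream joins
and figures consume, and its ±1.96 semantics are preserved. Genes with no
variance and no mean difference get `z = 0`. Populations with fewer than
`n_min` cells per condition (default 20) are skipped with a note.
Cell-cycle and mitochondrial-fraction regression are omitted: they shape
embeddings, not the gene-level Z-vs-m6A join computed here.

The scatter table joins per-population Z results with `density_cds` and
flags `top20_m6a` (top 20% of the joined universe), `down` and `up`.
Enrichment of the flagged sets against gene-set collections delegates to
the hypergeometric machinery; an optional `fdr_cut` restricts the
selection to FDR < 0.05, since Z-only and Z+FDR selections are both in
use depending on the figure being reproduced. Occupancy shifts between
conditions across populations are tested with Pearson's chi-square
(no continuity correction).

## The synthetic-data generator

The generator (`sim_config()`, `simulate_dataset()`) defines the study
conditions under which the pipeline is validated:

* **Transcriptome** — 50 transcripts (one per gene) of 1.2–3 kb, 1–3
  exons, random strand, each on its own chromosome; 20% 5' UTR, 60% CDS
  (rounded to codons), remainder 3' UTR. Random sequence at these lengths
  guarantees abundant DRACH positions (≈1.8% of positions).
* **Sites** — Poisson-planted at 5 per kb, only at DRACH-centred A's.
  Positions follow a mixture: weight 0.8 on a Gaussian kernel (sd 50 nt)
  centred at the stop codon, remainder uniform — reproducing the
  canonical stop-codon-biased metagene. Per-site methylation
  stoichiometry is uniform on [0.3, 1], the range in which an
  antibody-based assay detects sites reliably.
* **Tag libraries** — negative-binomial unique-tag counts (dispersion 8)
  per position, three replicate pairs with per-replicate depth factors.
  Input mean coverage is 15 per position at unit expression (log-normal
  expression, sd(log) 0.6); miCLIP background is 5, elevated by a factor
  `1 + 10 × methylation` within the 21-nt window of each site. The 10×
  enrichment at a fully methylated site is a declared simulation choice —
  assays do not report it. These depths correspond to a deeply sequenced
  experiment in which site recovery is reliable (precision ≈ 1, recall
  ≈ 0.9 at the defaults). Crosslink mutations are binomial at rate 0.2 at
  `site + 1` nt, background rate 0.001 elsewhere.
* **Translation efficiency** — `log TE = β × standardized(true CDS
  density) + N(0, 0.5)` with β = 1: the TE signal is planted in the CDS
  region only, so region comparisons have a known answer.
* **Single cells** — two conditions × 500 cells over four populations
  (proportions 0.45/0.2/0.15/0.2), three markers per population at 8-fold
  elevation, negative-binomial UMI counts (dispersion 2) with log-normal
  per-gene base means (meanlog 0, sdlog 1 — a moderately expressed panel
  in which a normal-approximation Z is meaningful). The knockout
  multiplies means by `1 − d` for a planted down set and `1 + u` for a
  planted up set (d = u = 0.5, 5% of genes each). The up set is sampled
  from the top 30% of true CDS m6A density, emulating the observed
  coupling between heavy CDS methylation and up-regulation after writer
  loss; this coupling is what makes the "red dot" enrichment a property
  of the design rather than an accident.

Every generator is deterministic under the configuration seed, and truth
tables (site positions and stoichiometry, TE effects, knockout sets,
population labels) are returned and written alongside the data so that
recovery is measured only in test code.

**What the generator does not emulate:** read-level artifacts (the
simulation starts from deduplicated tag counts, not FASTQ), isoform
mixtures, PCR chimeras, doublets, ambient RNA, batch effects, and
cell-cycle structure within populations. Passing tests therefore
demonstrate that the statistical machinery recovers planted structure
under idealized sampling noise — not that any particular real library is
free of those artifacts.

## Numerical and design choices

* Quintile ties break lexicographically by gene id; all orderings in the
  pipeline are stable, which is what makes end-to-end byte-determinism
  achievable.
* BH adjustment is used wherever multiplicity arises (candidate
  positions, gene sets, per-population genes).
* `z = 1.96` exactly is *ns*; thresholds are strict as printed.
* Window clipping, not mirroring, at transcript ends.
* Zero-input sites are dropped rather than smoothed (default `eps = 0`).
* The exact/approximate Wilcoxon switch is at `n_a + n_b ≤ 12` without
  ties.
* Problem sizes used by the validation suite: 50 transcripts × 3
  replicates for site-calling recovery; 500 genes for TE integration
  (200 simulation replicates for null calibration); 2000 genes × 1000
  cells for single-cell calibration and recovery. These sizes give stable
  Monte-Carlo estimates of the properties being checked while keeping a
  full validation run in the order of a minute or two.

## Known limitations

* One transcript model per gene; no isoform-aware site assignment.
* The binomial background model assumes a single global background
  mutation rate; real libraries show position- and context-dependent
  error profiles.
* The Welch-type Z understates dropout structure in very sparse genes;
  for deeply sparse data a hurdle or pseudobulk model is preferable.
* Hypergeometric enrichment ignores gene-length bias.
* The simulation's enrichment factor (10×) and NB dispersions are
  declared choices, not estimates from any particular dataset.
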