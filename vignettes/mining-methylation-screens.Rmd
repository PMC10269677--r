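---
title: "Mining regulators from a paired m4C methylome: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining regulators from a paired m4C methylome: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methscreen)
```

## The model

`methscreen` compares two call-level methylomes — wild type (WT) and a
methyltransferase-deletion mutant — under a deliberately simple model: a
methylome is a *set of keys* `(seqid, position, strand, mod_type)`, and a
site is **lost** exactly when its key occurs in WT and not in the mutant.
Kinetic evidence such as fraction-modified estimates is not modelled; the
only quality knob is an optional score floor (`minScore`) applied to both
samples before differencing, which keeps the difference deterministic and
order-independent. Calls on either strand inside a CDS count toward that
CDS — adjacent opposite-strand m4C pairs are common at palindromic motifs
and should not be halved.

Per gene `g` with CDS length `L` and WT CDS site count `w`:

* site-loss fraction = `lost / w` (defined as 0 when `w = 0`: such a gene
  can never pass the screen, and reports stay numeric);
* abundance-loss fraction = `lost / L` — the number of m4C-methylated CDS
  sites per CDS base, the strategy's second screening axis;
* the same statistics over an upstream promoter window.

### Promoter window

The promoter is the `promoterLen` bases upstream of the CDS on the
coding-strand side (upstream of `start` for `+` genes, of `end` for `-`
genes), clipped at contig position 1. The default of 300 bp is a common
bacterial promoter-region width and comfortably includes regulatory sites
a few bases upstream of the start codon (the motivating data set has a
documented site 9 bp upstream of its top candidate).

### Rounding

All printed percentages round **half-up** on the percent scale
(`floor(x * 10^d + 0.5) / 10^d`), not half-to-even: this reproduces every
published loss figure in the worked examples, including 7/8 → 88%. The
screen's abundance comparison is applied *after* rounding to one decimal
percent (`>= 1.0%`), because screened tables print genes at exactly "1%";
the site-loss comparison is strict (`> 80%`). Screen membership is
identical under both readings for the published table, and the choice is
recorded here once rather than left implicit in the code.

## Dense pathway regions

The region caller uses **fixed, non-overlapping 100-ordinal bins anchored
at ordinal 0**, merging adjacent bins whose pathway-gene density strictly
exceeds the threshold (default 10%). Published regions of this kind start
and end on multiples of 100 with widths of 100–200 ordinals, which is
exactly what fixed-100 binning plus adjacency merging produces; a sliding
window is not needed for that behaviour and is not implemented. Density is
computed over the genes *present* in a bin rather than over `binSize`, so
annotation gaps do not dilute density; the two denominators coincide for a
gap-free annotation. Region spans are half-open `[start, end)` — the label
`orf700-orf900` therefore includes ordinal 899 and excludes 900 — and a
single conversion point turns 1-based inclusive genomic coordinates into
0-based half-open BED at emission.

## Screening and ranking

Candidates must be regulator-annotated (case-insensitive keyword match on
the product text; the default list — regulator, regulatory protein,
transcription factor, sigma factor — is configurable because annotation
pipelines differ in how they label the regulator complement), pass both
loss thresholds, and have at least `minWtSites` WT CDS sites (default 1;
no extra floor is imposed because the site-loss definition already
excludes siteless genes). Promoter loss is a *ranking* signal, not a
filter: screened tables legitimately keep rows with promoter loss 0.
Ranking is the total order (in dense region, promoter loss, CDS loss,
abundance loss, ascending ordinal), so permuting the input cannot change
the result.

## DE sign consistency

Significance per time point defaults to `|log2FC| >= 1` and adjusted
`p <= 0.05`; when a table carries no adjusted p-values the call falls back
to the fold-change rule alone, and the fallback is logged. The published
crossover table prints no p-values and no DE criterion; all twelve of its
genes exceed |log2FC| = 1.17, so the default threshold reproduces the
printed intersection while remaining configurable. A gene is `up` when
every fold change is strictly positive, `down` when strictly negative,
otherwise `inconsistent` — a zero fold change can never be "the same
direction". The decision is invariant to time-point order.

## The synthetic-data generator

The generator emulates the *structure* the pipeline exploits, not the
sequence biology:

* **Annotation** — `nGenes` single-interval CDS tiled on one contig with
  150 bp spacing, lengths Normal(900, 225) floored at 300 bp and forced to
  whole codons, random strands, 8% regulator-style products. The scale
  mirrors a streptomycete chromosome (order 10^3–10^4 ORFs).
* **Methylomes** — background genes draw Poisson site counts at
  `siteRate = 8` per kb over CDS and promoter. Planted candidate genes
  instead receive a *deterministic* CDS site count at
  `plantedSiteRate = 13` per kb plus at least one promoter site. The
  elevated density is a property of the system being emulated:
  methyltransferase target genes in the motivating screen carry 1.0–1.7%
  CDS m4C density (13/kb is the midpoint), visibly above the genomic
  background, and a planted "candidate" with background density would not
  be a candidate under the abundance axis at all. The mutant removes every
  site of every planted gene and an independent `backgroundLossRate = 0.3`
  fraction of the rest — matching the roughly one-third genome-wide site
  reduction observed in this kind of knockout.
* **Pathway table** — Bernoulli membership at 0.3 inside planted ordinal
  spans, 0.02 outside (mirroring ~270 assigned genes clustered in a few
  regions of a ~7,000-ORF genome).
* **DE tables** — planted genes get `±4` log2FC plus N(0, 0.3) noise at
  every time point with adjusted p = 0.001; null genes get N(0, 0.3) with
  p = 0.9.

Each generator seeds its own RNG stream and restores the caller's state;
`simulateStudy()` derives per-stage seeds from one master seed, so any
stage can be regenerated independently and byte-identically.

**What passing tests do and do not show.** The generator plants clean,
complete losses over an independent background; real methylomes have
motif-driven site placement, partial methylation, coverage-dependent call
quality and strain-specific annotation noise. Recovering planted truth
therefore validates the *logic* of the screen (set difference, binning,
thresholds, ranking, consistency), not its biological sensitivity on any
particular organism.

## Numerical and degenerate-input choices

* Duplicate call keys collapse to the highest score at read time
  (order-independent); unknown modification tokens are skipped with a
  warning, malformed GFF3 lines abort with the line number.
* Both SMRT basemods layouts are accepted: the type token in column 3 or a
  `type=` attribute (the attribute wins over a generic `modified_base`).
* Genes on contigs absent from both methylomes yield all-zero deltas with
  a warning rather than an error, so one stray plasmid annotation cannot
  abort a genome-wide run.
* Overlapping genes are permitted; a call may count toward multiple genes.
* An empty region list, empty candidate table or header-only input all
  flow through and produce valid empty outputs.

## Problem sizes

The shipped tests run the generator at 300–2,000 genes (roughly 3,000–20,000
sites), 20-seed recall/precision sweeps at 600 genes, and 200-case
randomized invariant checks against brute-force oracles of at most 50
calls; these sizes keep the complete suite under two minutes while leaving
every code path exercised at realistic density.

## Known limitations

* Single-interval bacterial CDS only; multi-part CDS are rejected.
* No statistical test on methylation differences — the screen is a
  deterministic threshold rule, as in the strategy it implements.
* The abundance metric divides by CDS length in bases; published tables of
  this kind occasionally print slightly different abundance figures
  (e.g. 1.3% where 9/621 = 1.45%), suggesting an unstated denominator
  variant. The package documents and keeps the transparent definition.
* No motif, kinetic (IPD) or read-level modelling.
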