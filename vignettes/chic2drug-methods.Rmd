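---
title: "Methods: chromatin-interaction-based drug repositioning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chromatin-interaction-based drug repositioning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scientific background

Genome-wide association studies (GWAS) of autoimmune rheumatic diseases —
rheumatoid arthritis (RA), psoriatic arthritis (PsA), juvenile idiopathic
arthritis (JIA) — have mapped hundreds of risk loci, but the associated
variants are overwhelmingly non-coding. They concentrate in enhancers,
which can regulate genes hundreds of kilobases away, skipping over the
nearest gene entirely. Annotating loci by proximity therefore misidentifies
the causal gene, and with it the therapeutic target.

Promoter Capture Hi-C (CHi-C) measures which restriction fragments of the
genome are in physical contact with gene promoters in a given cell type.
When a fragment containing disease-associated variants contacts a promoter,
that contact is direct evidence for which gene the risk enhancer regulates.
This package implements the resulting target-nomination pipeline: risk loci
→ interacting, chromatin-state-consistent, expressed genes → existing drug
targets → repositioning candidates, with a pathway-level refinement step.

# The data model

All genomic intervals are **0-based, half-open** in memory and on disk
(BED convention); SNP positions are 1-based single coordinates (dbSNP
convention) and converted internally. Inputs are:

| Input | File | Content |
|---|---|---|
| Restriction fragments | `fragments.bed` | Gap-free, sorted, non-overlapping tiling per chromosome (HindIII-scale, ~4 kb) |
| Chromatin states | `segments_<cell_type>.bed` | ChromHMM 15-state segmentation per cell type |
| Genes | `genes.bed` | Gene body with strand; the TSS is the strand-aware 5′ end |
| Interactions | `interactions.tsv` | Fragment pairs with a confidence score per cell type |
| SNPs | `snps.tsv` | Index SNPs and their LD proxies with r² |
| Expression | `expression.tsv` | Gene × cell type expression values |
| Drug targets | `drug_targets.tsv` | Drug, target gene, approval groups, indication text |
| Reported genes | `reported_genes.tsv` | Gene(s) the source GWAS attributed to each locus |
| Disease terms | `disease_terms.yaml` | Name variants per disease for indication matching |
| Pathways | `pathways.gmt` | Gene-set collection for enrichment |

Validators enforce these contracts at load time; violations raise classed
conditions (`chic2drug_parse_error`, `chic2drug_validation_error`), and each
pipeline stage wraps failures with its stage name
(`chic2drug_stage_error`).

# Pipeline stages and their parameters

## LD blocks (`build_ld_blocks`)

Each index SNP is grouped with proxies at `r2_threshold` (default **0.8**,
the conventional "high LD" cutoff). The block's fragments are, by default,
exactly those hosting the index SNP or a passing proxy
(`block_mode = "snp"`). The alternative `"span"` mode takes every fragment
under the block's convex hull; it is more permissive and suits analyses
that distrust proxy completeness. We default to `"snp"` because CHi-C
evidence is fragment-resolved: a fragment with no associated variant in it
carries no association signal.

## Chromatin-state calls (`call_fragment_states`)

A fragment is *enhancer* in a cell type if it overlaps (≥ `min_overlap`
bp, default 1) a segment in state `6_EnhG`, `7_Enh` or `12_EnhBiv`, and
*promoter* for `1_TssA`, `2_TssAFlnk` or `10_TssBiv` — the enhancer- and
promoter-class states of the Roadmap 15-state ChromHMM model, including the
bivalent forms because bivalent regulatory elements are common in immune
cells. A fragment can be both. Unknown state labels trigger a single
warning, not an error, so segmentations with extra states degrade
gracefully.

## The interaction filter (`filter_candidates`)

A gene G is a candidate for locus L when there exist a cell type c and an
interaction (f₁, f₂) with score ≥ `score_threshold` (default **5**, the
CHiCAGO convention for a confident call) such that:

* f₁ belongs to L's LD-block fragments and is enhancer-state in c,
* f₂ is promoter-state in c and contains G's TSS
  (`gene_mode = "tss"`, default), and
* G is expressed (≥ `expression_threshold`, default **1**) in some
  relevant cell type.

The same-cell-type requirement for the enhancer call, promoter call and
interaction is the crux of the filter: chromatin contacts and regulatory
states are cell-type specific, and mixing them across cell types
manufactures false candidates. The pooled candidate list is the union of
the per-cell-type lists — a property the test suite asserts directly.

`gene_mode = "body"` instead accepts any gene whose body overlaps the
promoter fragment; it is offered for annotations without reliable TSS
calls, at the cost of over-counting genes near fragment boundaries.
Interactions are undirected: files may list either fragment first, and
`canonicalize_interactions` orders pairs by coordinate and collapses
symmetric duplicates to the maximum score.

## GWAS comparison (`categorize_loci`)

Each locus falls in exactly one category: `NO_CHIC_GENES` (no candidate at
all), `0` (candidates, but the GWAS-reported gene is not among them), or
`1`, `2-5`, `6+` (the reported gene is recovered, binned by candidate
count). Reported-gene matching is case-insensitive and accepts
comma-separated multi-gene reports; a blank or missing report yields `NA`
and is excluded from summaries. The category boundaries (1 / 2–5 / 6+) make
the recovery bins comparable across loci of very different candidate
multiplicity.

## Drug repositioning (`map_drug_targets`, `classify_current_use`)

Candidates are joined to the drug–target table on the normalised gene
symbol (upper-cased, trimmed). Optionally only drugs in given approval
`groups` (e.g. `"approved"`) are kept. A drug is *currently used* for a
disease when its free-text indication matches one of the disease's name
variants — by lower-cased substring containment by default, or by
`match_mode = "token"` (every token of the term present), which tolerates
re-ordered phrasing like "arthritis, juvenile" at the cost of occasional
over-matching. Everything identified but not currently used is
*repositionable*; per disease and overall, `n_drugs = n_current +
n_repositionable` by construction.

## Pathway refinement (`enrich_pathways`, `refine_and_expand`)

Per disease, the pooled candidate list is tested against each pathway with
a one-sided Fisher's exact test: with k overlap genes, K pathway genes, n
candidates and N universe genes, the p value is the upper hypergeometric
tail `phyper(k − 1, K, N − K, n, lower.tail = FALSE)`. One-sided because
only *over*-representation nominates targets. P values are BH-adjusted
across pathways within a disease and called significant at `alpha`
(default 0.05).

The default universe is the union of all genes in the supplied pathway
collection — the standard choice of over-representation tools, since genes
absent from the knowledge base are untestable. `universe = "annotated"`
(all genes in the annotation) and `"expressed"` (all genes passing the
expression threshold) are available when the candidate list should be
judged against the whole genome or the transcriptome.

The analysis is rerun on each cell type's own candidate list to label each
significant pathway: `Both` (significant in every per-cell-type run), a
single cell-type name, or `Pooled-only` (only the combined list reaches
significance — evidence spread across cell types).

Refinement keeps candidates belonging to at least one significant pathway
(a subset of the candidates by construction); expansion takes the union of
significant pathways' full gene sets and counts which *additional* genes
are drug targets, widening the repositioning search space beyond the
interaction-supported genes.

# The synthetic-data generator

`generate_fixture(fixture_config())` builds a complete study with planted
ground truth. It is a first-class deliverable, not a test helper: it is the
only way to validate the pipeline end to end, because every real-data stage
(CHi-C calls, ChromHMM segmentations, GWAS catalogs, DrugBank) is a
moving external resource.

## What it emulates

* A per-disease chromosome tiled gap-free by fragments with lengths
  `max(1500, N(mean = 4000, sd = mean/6))` — the HindIII fragment-size
  scale.
* Loci laid out on a fixed fragment grid (SNP fragment at offset 10,
  distractor gene at 30, main promoter at 40, extra promoters at 42–50),
  with the orientation flipped on even loci so both interaction directions
  occur.
* Two cell types (GM12878, a B-lymphoblastoid line, and primary T cells —
  the classic immune CHi-C pair), 8 proxies per index SNP, interaction
  scores straddling the threshold, and messy-but-valid inputs: lowercase
  reported genes, comma-separated reported lists, an experimental-group
  drug.

## Archetypes

Every locus is drawn from one of eight archetypes, each breaking (or
satisfying) exactly one link of the evidence chain:

| Archetype | Planted property | Expected outcome |
|---|---|---|
| `POSITIVE` | full evidence chain, gene not reported | category `0` |
| `NO_ENHANCER` | SNP fragment lacks enhancer state | no candidates |
| `NO_PROMOTER` | partner fragment lacks promoter state | no candidates |
| `NOT_EXPRESSED` | target gene below expression threshold | no candidates |
| `NO_INTERACTION` | interaction score below threshold | no candidates |
| `REPORTED_ONLY` | one candidate, equal to the reported gene | category `1` |
| `REPORTED_MULTI` | 2–5 candidates incl. the reported gene | category `2-5` |
| `REPORTED_MANY` | 6+ candidates incl. the reported gene | category `6+` |

The three `REPORTED_*` variants exist so every locus category is populated
and the category boundaries (5 vs 6) are exercised.

The knowledge base plants, per disease: two currently-used drugs, three
repositionable ones (one only `experimental`), a multi-disease drug, two
*absent* controls targeting distractor genes (must never be identified),
and two drugs targeting pathway-expansion-only genes. One pathway per
disease contains exactly the `REPORTED_*` candidates plus a few
non-candidate extras — so it is the only significant pathway, refinement is
a *proper* subset of the candidates, and expansion finds real additional
targets. Twenty-five background pathways drawn from a 300-gene background
pool keep the multiple-testing correction honest.

## Determinism and numerics

All randomness runs under a single `withr::with_seed(config$seed)` scope,
so a config fully determines every file byte. Values written to disk are
rounded first (r² to 4 decimals, scores and expression to 3), which makes
TSV round-trips exact: the pipeline produces byte-identical outputs whether
fed in-memory data or reloaded files. Problem sizes (60 loci: RA 30,
PsA 16, JIA 14; 25 background pathways; 60-fragment loci) are the package's
own defaults, chosen to exercise every archetype per disease at realistic
scale while keeping a full run in seconds.

## What it does not emulate

No real LD structure (proxies are placed, not drawn from a population), no
distance-decay in interaction scores, no biological replicate noise, no
gene-density variation, and indication texts are templated rather than
scraped. The generator's purpose is *verifiability* — planting a known
answer behind every stage — not cohort realism.

# Numerical and testing notes

* Fisher tails use `stats::phyper`; the test suite cross-checks them
  against an exhaustive `choose()`-sum enumeration over all tables with
  N ≤ 30 (agreement within 1e-10) and against `stats::fisher.test`.
* BH adjustment uses `stats::p.adjust`; tests compare against an
  independent step-up implementation on 1000 random p-vectors.
* Interval overlap uses `GenomicRanges::findOverlaps` after converting
  BED half-open coordinates to 1-based closed ranges; tests compare
  against a hand-written linear scan on 1000 random queries, including
  zero-width and boundary-touching intervals.
* Threshold monotonicity (raising score, r² or expression thresholds never
  enlarges the candidate set) and refinement containment are asserted as
  properties over parameter grids, not at single points.
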