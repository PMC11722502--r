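---
title: "Methods: variant-to-gene mapping from capture Hi-C with integrative scoring"
author: "chicv2g"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: variant-to-gene mapping from capture Hi-C}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chicv2g)
```

## Overview

`chicv2g` connects fine-mapped GWAS risk variants to candidate causal genes
through capture Hi-C chromatin interactions and ranks those genes with an
integrative evidence score. This vignette is the package's own account of
the model: assumptions, tunable parameters with defaults and units, what the
synthetic generator emulates, numerical conventions, and limitations. Every
number shown is computed by the package's tests or acceptance script, not
asserted from memory.

## Fine-mapping model

Per risk signal the credible causal variant (CCV) set is the **inclusive
union** of three routes:

* **Likelihood ratio.** From summary statistics only, with `z = beta / se`,
  the single-causal asymptotic approximation gives
  `LR_i = exp((z_i^2 - z_lead^2) / 2)`. Variants with `LR >= 1/100`
  relative to the signal's lead are kept. The exact likelihood behind the
  published "LLR < 1:100" phrasing is not derivable from summary data
  alone; this approximation is the standard one and is recorded in output
  metadata. The boundary is *inclusive*: the phrasing bounds the ratio
  against a variant, not the kept set, so a ratio of exactly 1/100 is kept.
* **LD expansion.** Variants with `r^2 > 0.8` (strict, per the stated
  wording) to the lead. Secondary signals — identified by conditional
  analysis — use this route exclusively; for primary signals it only
  rescues variants absent from the summary statistics ("not genotyped").
* **Bayesian membership.** Credible-set membership is consumed from a file
  (one row per variant × signal); the posterior computation itself is out
  of scope.

Fine-mapping windows are **inputs**, carried as optional
`chrom`/`region_start`/`region_end` columns on the signals table. The LLR
criterion is only meaningful within a locus: against variants of another
genome-wide-significant locus the ratio is ~1 regardless of causality, so
`fine_map_signals()` restricts the summary records to each signal's window
when one is provided.

Set bookkeeping obeys inclusion–exclusion exactly; with the published
per-method cardinalities (1,892 LLR/LD; 1,477 Bayesian; 1,421 shared) the
union has 1,948 members, which the acceptance suite reconstructs from
synthetic id sets.

## Restriction fragments, bins, and adjacency

The dual-enzyme digestion model cuts at `^GATC` (offset 0) and `G^ANTC`
(offset 1, `N` = any base); the published motif typography is ambiguous
about offsets, so the kit's convention was adopted and both offsets are
configurable. `N` in the *genome* never matches a motif. Cuts at a sequence
edge would create empty fragments and are dropped; fragments tile each
chromosome exactly (asserted per chromosome in tests).

Bins group `k = 4` consecutive fragments (trailing partial bins retained,
never spanning chromosomes); `k = 1` reduces to single-fragment analysis.
Internally all fragment/bin intervals are 0-based half-open; rmap and
baitmap files are emitted 1-based inclusive in the CHiCAGO dialect and
round-trip bit-exactly. CHiCAGO caller settings for one- and four-fragment
analyses (minFragLen/maxFragLen/binsize/maxLBrownEst = 75/1200/2000/150000
and 150/5000/8000/600000) are recorded as manifest metadata only —
interaction calling is consumed, not reimplemented.

A variant's **primary bin** contains its position; a window of ±500 b
(inclusive at both ends) is tested against the variant's *immediately
neighbouring fragments*, and any neighbour overlapping the window
contributes its bin as adjacent. The window test is on fragments, then
mapped to bins, mirroring the assay logic (cross-linking resolution and
incomplete digestion blur fragment boundaries). Interactions are read from
primary ∪ adjacent bins. The rule never adds a non-neighbouring bin even if
a window spans two fragments in one direction; this was left as the
narrower reading.

## Promoters

Three definitions coexist and are all used for linking:

* melanocyte ChromHMM promoter states: PromU, PromD1, PromD2, TssA, PromP,
  PromBiv, Tx_Reg (imputed model, two cultures, unioned);
* melanoma ChromHMM promoter states: 1_TssA, 2_PromWkD, 3_TssWkP;
* global: TSS ± 2.5 kb for every protein-coding transcript, clamped at
  chromosome bounds.

Windows are closed intervals in 1-based coordinates (the simplest reading
of "±2.5 kb of a TSS"); book-ended intervals merge so downstream logic sees
maximal regions. Genes are assigned where a promoter overlaps TSS ± 2.5 kb
of any transcript (ChromHMM promoters may assign non-coding transcripts;
the global definition coincides with its own window by construction and is
treated as identical). Unknown state labels are ignored but counted.

The same vocabulary registry carries the enhancer states per context;
enhancer ∪ promoter defines "regulatory" for the evidence ladder.

## Linking and distance

Interaction calls with score ≥ 5 (inclusive) are retained;
trans-chromosomal records are dropped with a log count (nomination is *cis*
only). Loops are used symmetrically — a CCV may sit at either end. Each
loop touching a CCV's primary or adjacent bins links the variant to every
gene of every assigned promoter overlapping the other end; variants
physically inside a promoter link by a second, distinguishable mechanism
(`promoter_overlap`), kept as separate records even when a loop exists
within the same promoter.

Distance is measured variant-position to the nearest TSS of the linked gene
among the target promoter's transcripts — chosen for determinism, since the
published wording ("from the CCV to the target gene promoter") fixes no
edge rule. Classes: `overlap` (0), `lt_100kb` (0, 100 kb), `kb100_to_1Mb`
[100 kb, 1 Mb] (both ends inclusive; ">1 Mb" is strict), `gt_1Mb`. A loop
link is flagged `alt_promoter` when the same (variant, gene) pair also has
a promoter-overlap link and the two promoters lie ≥ 10 kb apart
edge-to-edge.

## Evidence ladder and high-confidence set

Per (signal, gene), flags are evaluated over the **same linking variant**:

1. `linked` — any loop or promoter-overlap link;
2. `var_regulatory` — that variant in an ATAC peak *or* an
   enhancer/promoter ChromHMM state, either cell context (the inclusive-OR
   definition; the stricter ATAC-and-ChromHMM set is also reported);
3. `var_mpra_sig` — additionally FDR-significant in the reporter assay in
   either context (missing rows mean *untested*, never imputed);
4. `var_marginal_eqtl` — additionally a marginal eQTL for the gene at
   p < 0.05 (ordinary least squares of expression on dosage plus
   covariates; the test matches a normal-equations oracle to 1e-10 and its
   type-I error is calibrated in the acceptance suite).

The nesting `marginal ⇒ MPRA ⇒ regulatory ⇒ linked` is an invariant:
the scorer *rejects* violating records rather than silently rescoring,
since a violation means the records were not built by the evidence module.
The high-confidence set is the genes (with companion variant and signal
sets) reached at level ≥ 3. Whether regulatory and MPRA evidence must share
a cell context is unspecified in the source; contexts are pooled, with
per-context flags retained so the stricter reading can be recovered.

Expression support uses the stated filter — a gene is dropped iff the
fraction of samples with RSEM < 0.1 *strictly* exceeds 20% (exactly 20% is
retained) — and the median across samples of the within-sample percentile
rank among retained genes.

## Integrative score

```
score = 6                                   if eQTL/TWAS colocalization
      = ladder (0-4) + 2 * [meQTL/MWAS]     otherwise
      + [melanoma driver] + [pan-cancer driver]
```

The +2 methylation points sit inside the "remaining genes" branch and do
**not** stack on eQTL/TWAS genes — this is what makes the published
TWAS+MWAS+driver example score 7 (6 + 1) rather than 9. Driver points apply
to all nominated genes. Exhaustive enumeration of the 80 valid evidence
combinations gives a range of exactly [0, 8], the score is monotone in
every flag, and the total always equals the sum of its components (all
asserted in tests). A gene nominated only by a protein-altering variant
(no link) is retained with `protein_coding_nomination = TRUE` and ladder 0.

## Synthetic universe

The generator's defaults state one desk-scale world and are not tuned to
tests:

| parameter | default | rationale |
|---|---|---|
| chromosomes × length | 1 × 600 kb | hosts 10 genes in ≥ 8 kb slots with room for 20–80 kb enhancer placement |
| genes | 10, 2–4 kb, random strand | one candidate target per signal |
| signals × variants | 10 × 15 | matches the stated desk-scale recovery scenario |
| causal effect λ | 6 | a genome-wide-significant lead (z ≈ 6, p ≈ 2e-9) |
| LD decay | r = exp(−2e−4·d) | tight block: r ≈ 0.82 at 1 kb, 0.45 at 4 kb |
| fraction regulatory | 1 | every causal inside a planted enhancer |
| loop score range | [5, 15] | all planted loops pass the score-5 filter |
| decoy rate | 0 | decoys added per true loop when > 0 |

Placement constraints make planted truth well-defined: enhancer fragments
lie 20–80 kb from the target TSS, ≥ 6 kb from *every* TSS (so no causal
accidentally sits in a promoter), and ≥ 12 kb from other signals' enhancers
(so no variant cloud shares or neighbours another signal's loop-anchor
bin). Variants are sampled on fragments, never on cut-site motifs, so
digestion and variant placement cannot interact. Decoy loops connect a
causal's bin to the promoter bin of a non-target gene — never a causal to
its true gene — so every false positive is attributable. Z-scores are drawn
from a multivariate normal with mean `r_(i,causal)·λ` and the signed
exponential-decay correlation (positive-definite by construction; any
non-PD input is repaired by logged diagonal loading). `beta = z·se` with
`se` fixed at 0.02 — arbitrary but stated; only `z` matters downstream. One
master seed fans out to per-component sub-seeds through a fixed string
hash, so adding outputs never reshuffles existing ones; identical seeds
give byte-identical files.

What the generator does **not** emulate: realistic human LD panels (no
negative LD, no panel mismatch), sequence-level enhancer grammar, read-level
Hi-C noise, CHiCAGO's background model, multi-causal signals, or
trans-chromosomal contacts. A green planted-recovery test therefore
establishes that the pipeline's plumbing and boundary semantics are
correct — not that the method would attain this accuracy on real data,
where the published analysis reports much lower regulatory fractions.

## Numerical conventions

* Boundaries: CHiCAGO score 5.0 retained; r² = 0.8 excluded; LR = 1/100
  included; 20% low-expression samples retained; ±500 b window inclusive;
  100 kb and 1 Mb both belong to the middle distance class; 10 kb
  alternative-promoter separation inclusive.
* Coordinates: 0-based half-open internally for fragments/bins; 1-based
  closed for variants, promoters, and all ChromHMM/ATAC intervals after
  import; BED read/write converts at the boundary.
* Tie-breaks: the best variant per (signal, gene) is the deepest ladder
  level, then lowest GWAS p, then lexicographic id; gene ranking ties break
  lexicographically.
* Degenerate inputs: empty sequences digest to nothing; constant dosage is
  untestable (marked, not errored); promoters without genes are flagged
  unassigned and excluded from nomination; a missing MPRA file yields an
  empty high-confidence set with a warning rather than a failure.

## Limitations

Interaction calling, Bayesian posterior computation, colocalization, TWAS
weights, VEP, and FDR estimation are all consumed as inputs by design. The
LLR approximation ignores covariate adjustment in the original likelihood.
The adjacency rule considers only immediate fragment neighbours. Distances
use variant-to-nearest-TSS; bin-midpoint distances would differ for wide
bins. The synthetic world plants exactly one causal per signal, so
multi-causal fine-mapping behaviour is untested beyond the union logic.
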