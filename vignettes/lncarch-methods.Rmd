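---
title: "Genomic architecture and expression dynamics of lncRNA-protein gene pairs: methods"
author: "lncarch authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{lncarch methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncarch)
```

## Overview

Mammalian genomes interleave long non-coding RNA (lncRNA) genes with
protein-coding genes in recurring positional arrangements — antisense
overlaps, intronic nesting, shared bidirectional promoters, close intergenic
neighbourhoods. `lncarch` models the question of whether these *genomic
architectures* (GAs) are associated with distinct temporal expression
behaviour during a differentiation timecourse. The pipeline has four stages:

1. **Architecture classification**: each lncRNA gene is paired with its
   nearest protein-coding gene within 10 kbp and the pair is assigned one of
   19 GA classes, grouped into 5 super-classes.
2. **Differential expression**: a replicate-concordance rule (Kendall's
   $\tau$ on timepoint subsets) combined with an endpoint fold-change cutoff.
3. **Dynamic modes**: each timecourse is matched by Pearson correlation to a
   catalogue of eight "rate" and eight "magnitude" templates.
4. **Filtration cascade and enrichment**: lncRNAs are filtered through a
   nested sequence of conditions and the frequency shift of each GA class or
   mode at each step is tested with a hypergeometric tail, reported with
   fold enrichment and Bonferroni correction.

All stages operate on plain data structures (a `gene_set` of annotations, a
`SummarizedExperiment` of intensities), and a synthetic-data generator plants
known architectures, modes and correlation signs so that every stage can be
validated end to end.

## The architecture taxonomy

Internal coordinates are 0-based half-open on the forward strand; GFF3's
1-based closed coordinates are converted at the I/O edge and BED's are kept
as-is. Gene models are collapsed to one representative per gene (union span,
union exon set): classification is a property of gene loci, not of
individual transcript isoforms.

A lncRNA is *associated* when a protein-coding gene on the same chromosome
lies within `radius` = 10,000 bp of it by closest-edge distance (overlap
counts as distance 0). The associated pair is classified by the first
matching rule, evaluated in this order:

**Overlapping pairs** (suffix `_sense`/`_antisense` by strand relation to the
protein):

* `intronic_*` — the lncRNA lies wholly inside one intron of the protein.
* `exonic_*` — the lncRNA lies within the protein's span and the overlap
  touches only exonic sequence.
* `embedding_*` — one gene's span contains the other's and the overlap
  touches both exonic and intronic sequence.
* `head_to_head` — residual partial overlap at the two 5' ends (divergent);
  `tail_to_tail` — at the two 3' ends (convergent). When both end pairs fall
  inside the overlap (near-identical spans) the pair is treated as
  embedding.

**Non-overlapping pairs**:

* `promoter_associated_{sense,antisense}` — the lncRNA is contained entirely
  within the 1 kbp window immediately upstream of the protein TSS
  (promoter-proximal transcripts of the uaRNA/PROMPT kind), split by strand.
* `bidirectional_promoter_{1,5,10}kbp` — divergent orientation (opposite
  strands, lncRNA on the protein's 5' side) with TSS-to-TSS distance in the
  exclusive bins (0, 1000], (1000, 5000], (5000, 10000].
* `intergenic_{upstream,downstream}_{1,5,10}kbp` — everything else, by side
  relative to the protein's orientation and closest-edge distance in the
  same bins.

Distance anchors differ deliberately: promoter sharing is a property of the
two TSSs, so bidirectional classes bin TSS-to-TSS distance, while intergenic
classes bin the closest-edge gap. "Upstream" is defined relative to the
protein's strand throughout.

Three points in this taxonomy were genuinely open and are package decisions:

* *Promoter-associated vs bidirectional.* An antisense lncRNA overlapping
  the upstream promoter window is always in divergent orientation (its TSS
  is necessarily the end nearest the protein), so a "non-divergent antisense
  window-overlapping" class would be geometrically empty, and a
  window-*overlap* rule would swallow every 1 kbp-distant bidirectional
  pair. Defining the promoter-associated classes by *containment* in the
  window separates the two cleanly: short promoter-proximal transcripts are
  promoter-associated, while longer divergent neighbours remain
  bidirectional, and same-strand upstream lncRNAs that merely reach into the
  window remain intergenic.
* *Same-strand partial overlaps.* Head-to-head and tail-to-tail are
  antisense configurations by definition. Residual same-strand partial
  overlaps are classified by the composition of their overlap region
  (exonic-only → `exonic_sense`, otherwise `embedding_sense`).
* *Super-classes.* `antisense` collects the four opposite-strand overlap
  geometries (embedding, exonic, head-to-head, tail-to-tail); `intronic`
  collects the within-gene geometries (`intronic_{s,a}`, `exonic_sense`,
  `embedding_sense`); the remaining eleven classes map by name onto
  `promoter_associated`, `bidirectional` and `intergenic`. The map is total
  and onto the five labels.

Ties in partner finding (equal edge distance on both sides) are broken by
the higher-priority GA class of the candidate pair, then lexicographically —
determinism is worth more than any particular convention here. A divergent
pair whose TSS distance exceeds 10 kbp (a long lncRNA with a small edge gap)
falls back to the intergenic classes so that no associated pair is left
unlabelled.

```{r taxonomy}
ga_classes()[, c("name", "superclass", "distance_bin", "orientation")]
```

## Differential expression

The study design this package emulates measured each gene at 4 timepoints
(0, 6, 24, 120 h) in two biological replicates, on arrays whose intensities
were deliberately *not* normalized (correlation- and rank-based statistics
downstream are insensitive to monotone scaling; with two replicates,
background correction introduced more artifacts than it removed). `lncarch`
therefore applies no normalization either; `expression_set()` accepts any
non-negative intensity matrix and users may pre-transform as they see fit.

A gene is **differentially expressed** when

* there is at least one subset of `subset_size` = 3 of the 4 timepoints on
  which the two replicate profiles agree with Kendall's $\tau >$ 0.6 —
  on three untied points $\tau \in \{\pm 1, \pm 1/3\}$, so this is exactly
  perfect rank agreement on that subset ("concordant in any three of the
  four time points"); with more than two replicates the condition must hold
  for every replicate pair; and
* the fold change between the replicate-mean intensities at the first and
  last timepoints is at least 1.5, in either direction
  ($\max(m_0, m_T)/\min(m_0, m_T) \ge 1.5$) — both induced and repressed
  genes count.

`kendall_tau()` uses the $\tau_b$ tie correction; the thresholds above are
calibrated for untied data, and ties (which synthetic integer data can
produce) only shrink $|\tau|$, making the rule conservative. Whether the
endpoint means or medians were the historical choice is unknowable from the
study's description; means are used, and `profile_stat` switches the
collapsing statistic used for correlation and mode assignment.

**Pair correlation** is Kendall's $\tau$ between the two replicate-mean
4-point profiles: "+" when $\tau \ge$ 0.6, "−" when $\tau \le -$0.6. On four
untied points $\tau \in \{0, \pm 1/3, \pm 2/3, \pm 1\}$, so the cutoff
admits exactly $|\tau| \in \{2/3, 1\}$ — this discreteness is verified by
exhaustive enumeration of all 24 orderings in the test suite.

## Dynamic modes

Two template families describe a 4-point timecourse ordinally:

* **Rate modes** — the $2^3 = 8$ sign triples of change between consecutive
  timepoints. For correlation each triple is embedded as its cumulative sign
  path anchored at 0 (signs $(+,+,-)$ → template $(0,1,2,1)$): the minimal
  numeric 4-vector whose consecutive differences carry the signs.
* **Magnitude modes** — eight low/high (0/1) patterns over the four
  timepoints: the step patterns up by 6/24/120 h, the 6–24 h pulse, and
  their four complements. Of the 16 possible 0/1 vectors this is the unique
  8-element set that covers the full up/down/transient vocabulary, is closed
  under complementation, and excludes the two constants (Pearson undefined).

`rate_signs()` follows the ordinal definition directly: per-timepoint
*medians* across replicates are differenced and only signs kept, with zero
differences mapped to "−" (a two-letter alphabet is required for "all eight
combinations"; the choice is configurable). `assign_mode()` instead follows
the correlation definition used for mode membership: Pearson $r$ of the
collapsed profile against all eight templates, argmax wins, ties broken by
enumeration order with a flag, constant profiles returned as unassignable
rather than as errors. Templates are indexed by timepoint *rank* (0,1,2,3),
not by hours — using hours would silently down-weight the early intervals
by the long 24→120 h gap, and the modes are ordinal patterns, not kinetic
fits.

No two templates, within or across families, are affinely equivalent with
positive slope (verified in tests), so argmax assignment is unambiguous on
noise-free templates.

## Filtration cascade and enrichment

The cascade applies five nested memberships to the lncRNA universe:

1. on the array (has an expression row),
2. differentially expressed,
3. additionally associated with a protein-coding gene,
4. whose partner is also differentially expressed,
5. and whose pair correlation is "+" or "−".

At each step the GA class, super-class and (optionally) mode frequency
tables are recorded; by construction each step's set is a subset of the
previous one and tables sum to step sizes — both properties are
property-tested on random synthetic datasets.

For a step with retained set of size $n$ and previous-step population of
size $N$, a class with $K$ members before and $k$ after is tested with the
hypergeometric tails $P(X \ge k)$ (over-representation) and $P(X \le k)$
(under); the smaller tail is reported with its direction. Fold enrichment is
the frequency contrast of the test itself:
$\mathrm{FE} = (k/n) \,/\, ((K-k)/(N-n))$, retained-set frequency over
removed-set frequency ($\infty$ flagged when the removed set lacks the class
entirely). Two tabulations are available: each class against all
non-members, and each ordered class pair restricted to the two classes'
members. Bonferroni correction uses the number of tests in the invocation
batch (one step × one tabulation × all labels) — a reproducible,
conservative family definition since no historical $m$ is recoverable.

## The synthetic-data generator

`simulate_annotations()` lays out one genomic "slot" per requested pair on a
synthetic chromosome: the protein-coding gene (8 kbp, two 2 kbp exons
flanking a 4 kbp intron) sits mid-slot and the lncRNA is placed by exact
arithmetic in the geometry of the requested class — overlap classes inside
the relevant exon/intron, distance-binned classes at gaps chosen inside the
correct bin. Slots are isolated by more than the association radius, so
partner-finding is unambiguous. Each slot is mirrored (coordinates
reflected, strands flipped) with probability 1/2, exercising both strands.
The construction is deliberately a *second implementation* of the geometry
rules — placement arithmetic, not rejection sampling through the classifier
— so the planted-class = recovered-class round-trip test is a genuine
two-implementation check, and it holds exactly at every seed.

`simulate_timecourses()` draws a mode per pair, scales its unit-range
template to intensities $I = b\,(1 + (\rho - 1)\,u)$ with baseline
$b = 100$ and dynamic range $\rho = 10$ (linear-scale array intensities at
which the 1.5-fold DE cutoff is meaningfully exercised), and adds
i.i.d. Gaussian noise with `noise_sigma` (default 0.2) on the unit-template
scale per replicate and timepoint, flooring intensities at $0.01\,b$. The
planted correlation sign determines the lncRNA's template: the partner's
("+"), its complement ("−" — both families are closed under
complementation), or an independently drawn template whose Kendall $\tau$
against the partner's is below the correlation cutoff ("none"; an
unconstrained draw could correlate perfectly by chance and make the planted
sign unrecoverable even at zero noise).

What the generator does *not* emulate: probe-level effects,
cross-hybridization, intensity-dependent variance, or the real class
frequency distribution of any genome. Passing recovery tests therefore
demonstrates the pipeline's internal consistency and noise robustness, not
biological conclusions about real arrays.

Problem sizes used by the test suite: per-mode recovery is estimated with
1,000 simulations per mode per noise level (recovery at $\sigma = 0.2$ is
≥ 90% for every mode in both families, and mean recovery is non-increasing
in $\sigma$ over $\{0, 0.1, 0.2, 0.4\}$); cascade integrity is checked on
100 random datasets of 19 pairs each; oracle equivalence covers all
hypergeometric parameterizations with $N \le 25$ and 1,000 random vectors
for Kendall's $\tau$.

## Numerical and degenerate-input choices

* Exclusive distance bins (0,1000], (1000,5000], (5000,10000]; an edge
  distance of exactly 10,000 bp is associated, 10,001 is not; abutting
  non-overlapping genes (gap 0) fall in the first bin.
* Kendall $\tau$ of a constant vector is `NA`, propagated as "no call"
  ("none" for correlation signs); constant profiles are "unassignable" in
  mode assignment.
* Hypergeometric tails are computed by `stats::phyper`, which is exact to
  machine precision over the ranges used (verified against integer-binomial
  enumeration in the test suite).
* Fold change errors on a zero endpoint mean (invalid upstream);
  `fold_enrichment` returns `Inf` when the removed set lacks the class, and
  0 when the retained set does.
* All randomness flows from a single integer seed per simulation spec;
  reruns are byte-identical.

## Limitations

* The 19-class taxonomy is a reconstruction from the class vocabulary used
  in the source study's prose; the promoter-associated sense/antisense split
  is its least certain element (see the taxonomy section for the choice
  made).
* Multi-transcript loci are collapsed per gene; isoform-specific
  architecture (e.g. an antisense overlap confined to one isoform) is out
  of scope.
* Each lncRNA is paired with exactly one nearest protein-coding gene;
  lncRNAs in dense clusters have secondary neighbours that are ignored, as
  are lncRNA–lncRNA pairs.
* The DE rule is tailored to the two-replicate, four-timepoint design; its
  generalization to more replicates (every replicate pair concordant) is a
  conservative convention, not an inference procedure with error control.
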