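# lncarch

Genomic architecture and expression dynamics of lncRNA–protein-coding gene
pairs.

Long non-coding RNA (lncRNA) genes are not scattered at random: they overlap
protein-coding genes in antisense, sit inside introns, share bidirectional
promoters, or flank genes at close range. `lncarch` is for transcriptomics
analysts who want to ask whether these *genomic architectures* (GAs) are
associated with distinct temporal expression behaviour in a replicated
short timecourse (the motivating design: 2 biological replicates at 0, 6,
24 and 120 h of induced differentiation).

The package provides:

* **Architecture classification** — each lncRNA is paired with its nearest
  protein-coding gene within 10 kbp (closest-edge distance; overlap = 0)
  and the pair is assigned one of **19 GA classes** grouped into **5
  super-classes** (antisense, intronic, intergenic, bidirectional,
  promoter-associated). Annotations come in as GFF3 or BED12, results go
  out as TSV and BED6+3.
* **Differential expression** — a gene is DE when its replicates are
  rank-concordant (Kendall's τ > 0.6) on some 3-of-4 timepoint subset *and*
  the endpoint fold change is ≥ 1.5 in either direction.
* **Pair correlation** — Kendall's τ between the replicate-mean profiles of
  a lncRNA and its partner; "+" at τ ≥ 0.6, "−" at τ ≤ −0.6.
* **Dynamic modes** — each timecourse is assigned by Pearson correlation to
  one of eight "rate" templates (all sign triples of change between
  consecutive timepoints, embedded as cumulative sign paths) or eight
  "magnitude" templates (low/high step and pulse patterns).
* **Filtration cascade + enrichment** — lncRNAs are filtered through the
  nested steps *on array → DE → protein-associated → partner DE →
  sign-correlated*; at each step the frequency shift of every class is
  tested with hypergeometric tails
  (retained vs removed set), reported with fold enrichment
  FE = (k/n)/((K−k)/(N−n)) and Bonferroni correction.
* **Synthetic data** — a generator that plants architectures by exact
  placement arithmetic and plants modes/correlation signs in noisy
  timecourses, so the whole pipeline is testable with no external data.

See `vignettes/lncarch-methods.Rmd` for the model, its assumptions and the
design decisions.

## Worked example

Simulate a dataset with one pair per architecture class (seed 42, noise
σ = 0.2), classify it, and run the cascade:

```r
library(lncarch)

spec <- simulation_spec(seed = 42, noise_sigma = 0.2)
ds   <- simulate_dataset(spec)           # genes, expression, planted truth
pairs <- classify_all(ds$genes, ds$genes)
table(pairs$superclass)
#>           antisense       bidirectional          intergenic            intronic
#>                   4                   3                   6                   4
#> promoter_associated
#>                   2

cascade <- run_filtration_cascade(pairs, ds$se, mode_family = "rate")
cascade
#> filtration cascade:
#>   on_array                           19
#>   differentially_expressed           16
#>   protein_associated                 16
#>   partner_differentially_expressed   11
#>   correlated                         9
```

All 19 lncRNAs are on the array; 16 pass the DE rule (the 3 failures are
transient planted modes whose endpoints move less than 1.5-fold under this
noise draw); all DE lncRNAs have partners by construction; 11 partners are
also DE; and 9 pairs correlate at |τ| ≥ 0.6 — close to the two thirds
planted as "+" or "−".

Which super-classes shifted at the DE step, retained (n = 16) versus
removed (3 of 19)?

```r
class_shift_tests(cascade, "differentially_expressed", "superclass")
#>                 label k K  n  N direction   p_value fold_enrichment p_adjusted
#> 1           antisense 3 4 16 19     under 0.5304438          0.5625          1
#> 2       bidirectional 3 3 16 19      over 0.5779154             Inf          1
#> 3          intergenic 4 6 16 19     under 0.2218782          0.3750          1
#> 4            intronic 4 4 16 19      over 0.4695562             Inf          1
#> 5 promoter_associated 2 2 16 19      over 0.7017544             Inf          1
```

At n = 19 nothing is significant after correction (p_adjusted = 1
throughout) — the point of the example is the bookkeeping: k of K class
members survive into the retained set of n, FE contrasts retained against
removed frequencies (`Inf` when the removed set lacks the class entirely).

One gene's timecourse and its mode call, against the planted truth:

```r
round(timecourse(ds$se, "LNC0001"), 1)
#>       t0     t6   t24  t120
#> r1 534.7  860.2 632.2 401.6
#> r2 426.1 1314.0 528.7   1.0
assign_mode(timecourse(ds$se, "LNC0001"), "rate")[c("mode", "r")]
#> $mode
#> [1] "transiently_activated_at_6h"
#> $r
#> [1] 0.9778864
ds$truth[1, c("ga_class", "planted_lnc_mode", "planted_sign")]
#>         ga_class            planted_lnc_mode planted_sign
#> 1 intronic_sense transiently_activated_at_6h            -
```

The rise-then-fall profile matches the planted "transiently activated at
6 h" template (r = 0.98) and the gene's planted intronic-sense architecture
and negative correlation with its partner flow through the cascade above.

A thin command-line wrapper is installed as `exec/lncarch`
(`lncarch simulate|classify|analyze`); it only forwards to
`run_simulate()`, `run_classify()` and `run_analyze()`, which write the
stage TSVs plus a `manifest.yaml` for bit-reproducible reruns.

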