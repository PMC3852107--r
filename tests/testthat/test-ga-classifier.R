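test_that("taxonomy is 19 classes mapping totally onto 5 super-classes", {
  tab <- ga_classes()
  expect_equal(nrow(tab), 19L)
  expect_equal(anyDuplicated(tab$name), 0L)
  expect_setequal(unique(tab$superclass), ga_superclasses())
  expect_equal(superclass_of("head_to_head"), "antisense")
  expect_equal(superclass_of("intergenic_upstream_5kbp"), "intergenic")
  expect_equal(superclass_of("bidirectional_promoter_10kbp"), "bidirectional")
  # distance bins are present exactly for bidirectional and intergenic classes
  expect_true(all((tab$distance_bin != "none") ==
                    (tab$superclass %in% c("bidirectional", "intergenic"))))
  expect_error(superclass_of("no_such_class"), "unknown GA class")
})

test_that("find_partner minimises edge distance within the radius", {
  lnc <- lnc_gene("L", 1000, 2000)
  far <- gene_set(list(prot_gene("A", 15000), prot_gene("B", 30000)))
  expect_true(is.na(find_partner(lnc, far)))  # min gap 13000 > 10000

  near <- gene_set(list(
    gene_annotation("A", "chr1", 2500, 3000, "+", biotype = "protein_coding"),
    gene_annotation("B", "chr1", 9000, 9500, "+", biotype = "protein_coding")))
  expect_equal(find_partner(lnc, near), "A")  # gap 500 beats 7000

  mix <- gene_set(list(
    gene_annotation("OV", "chr1", 1500, 5000, "+", biotype = "protein_coding"),
    gene_annotation("C", "chr1", 2100, 2600, "+", biotype = "protein_coding")))
  expect_equal(find_partner(lnc, mix), "OV")  # overlap counts as distance 0
})

test_that("find_partner tie-break is deterministic", {
  # equal gap 500 both sides; the pair yielding the higher-priority GA class
  # wins: upstream (Z, priority 14) beats downstream (A, priority 17)
  lnc <- lnc_gene("L", 10000, 11000)
  prots <- gene_set(list(
    gene_annotation("Z", "chr1", 11500, 12500, "+", biotype = "protein_coding"),
    gene_annotation("A", "chr1", 8500, 9500, "+", biotype = "protein_coding")))
  expect_equal(find_partner(lnc, prots), "Z")

  # equal gap and identical GA class on both sides -> lexicographically
  # smaller id. Left "+" and right "-" neighbours both put the lncRNA on
  # their 3' side: intergenic_downstream_1kbp either way.
  prots2 <- gene_set(list(
    gene_annotation("Z", "chr1", 8500, 9500, "+", biotype = "protein_coding"),
    gene_annotation("A", "chr1", 11500, 12500, "-", biotype = "protein_coding")))
  expect_equal(find_partner(lnc, prots2), "A")
})

test_that("classify_pair reproduces the canonical geometry verdicts", {
  # lncRNA wholly inside an intron, same strand
  prot <- gene_annotation("P", "chr1", 1000, 10000, "+",
                          exons = rbind(c(1000, 2000), c(9000, 10000)),
                          biotype = "protein_coding")
  lnc <- lnc_gene("L", 3000, 4000, "+")
  expect_equal(classify_pair(lnc, prot)$ga_class, "intronic_sense")

  # divergent non-overlapping pair with TSS distance 500
  prot <- gene_annotation("P", "chr1", 5000, 8000, "+",
                          biotype = "protein_coding")
  lnc <- lnc_gene("L", 1000, 4500, "-")
  cl <- classify_pair(lnc, prot)
  expect_equal(cl$ga_class, "bidirectional_promoter_1kbp")
  expect_equal(cl$tss_distance, 500L)

  # convergent 3' overlap
  prot <- gene_annotation("P", "chr1", 1000, 5000, "+",
                          biotype = "protein_coding")
  lnc <- lnc_gene("L", 4500, 7000, "-")
  cl <- classify_pair(lnc, prot)
  expect_equal(cl$ga_class, "tail_to_tail")
  expect_equal(cl$overlap_bp, 500L)
  expect_equal(cl$edge_distance, 0L)

  expect_error(classify_pair(lnc_gene("L", 0, 100, chrom = "chr2"), prot),
               "different chromosomes")
})

test_that("hand-built exemplars of all 19 geometries classify as expected", {
  p0 <- 100000L
  prot <- prot_gene("P", p0)  # exons [p0,p0+2000), [p0+6000,p0+8000)
  cases <- list(
    intronic_sense                = list(p0 + 2500L, p0 + 3500L, "+"),
    intronic_antisense            = list(p0 + 2500L, p0 + 3500L, "-"),
    exonic_sense                  = list(p0 + 500L, p0 + 1500L, "+"),
    exonic_antisense              = list(p0 + 500L, p0 + 1500L, "-"),
    embedding_sense               = list(p0 + 1000L, p0 + 3000L, "+"),
    embedding_antisense           = list(p0 + 1000L, p0 + 3000L, "-"),
    head_to_head                  = list(p0 - 1500L, p0 + 500L, "-"),
    tail_to_tail                  = list(p0 + 7500L, p0 + 9500L, "-"),
    promoter_associated_sense     = list(p0 - 900L, p0 - 100L, "+"),
    promoter_associated_antisense = list(p0 - 900L, p0 - 100L, "-"),
    bidirectional_promoter_1kbp   = list(p0 - 2000L, p0 - 500L, "-"),
    bidirectional_promoter_5kbp   = list(p0 - 6000L, p0 - 3000L, "-"),
    bidirectional_promoter_10kbp  = list(p0 - 11000L, p0 - 8000L, "-"),
    intergenic_upstream_1kbp      = list(p0 - 3000L, p0 - 500L, "+"),
    intergenic_upstream_5kbp      = list(p0 - 6000L, p0 - 3000L, "+"),
    intergenic_upstream_10kbp     = list(p0 - 11000L, p0 - 8500L, "+"),
    intergenic_downstream_1kbp    = list(p0 + 8500L, p0 + 10500L, "+"),
    intergenic_downstream_5kbp    = list(p0 + 11500L, p0 + 13000L, "+"),
    intergenic_downstream_10kbp   = list(p0 + 14000L, p0 + 16000L, "+"))
  for (cls in names(cases)) {
    g <- cases[[cls]]
    lnc <- lnc_gene("L", g[[1L]], g[[2L]], g[[3L]])
    expect_equal(classify_pair(lnc, prot)$ga_class, cls, label = cls)
  }
})

test_that("overlap-class priority resolves residual geometries sensibly", {
  p0 <- 50000L
  prot <- prot_gene("P", p0)
  # lncRNA containing the whole protein gene -> embedding
  expect_equal(classify_pair(lnc_gene("L", p0 - 1000L, p0 + 9000L, "-"),
                             prot)$ga_class, "embedding_antisense")
  # same-strand partial overlap spanning exon+intron -> embedding_sense
  expect_equal(classify_pair(lnc_gene("L", p0 + 1000L, p0 + 9000L, "+"),
                             prot)$ga_class, "embedding_sense")
  # same-strand partial overlap confined to an exon -> exonic_sense
  expect_equal(classify_pair(lnc_gene("L", p0 + 7000L, p0 + 9000L, "+"),
                             prot)$ga_class, "exonic_sense")
  # antisense 5' partial overlap confined to the first exon is head_to_head,
  # not exonic (exonic requires containment in the gene span)
  expect_equal(classify_pair(lnc_gene("L", p0 - 1500L, p0 + 500L, "-"),
                             prot)$ga_class, "head_to_head")
})

test_that("distance bins are exclusive and the radius is a hard cutoff", {
  p0 <- 50000L
  prot <- prot_gene("P", p0)
  prots <- gene_set(list(prot))
  gap_class <- function(gap) {
    lnc <- lnc_gene("L", p0 + 8000L + gap, p0 + 9000L + gap, "+")
    classify_pair(lnc, prot)$ga_class
  }
  expect_equal(gap_class(1L), "intergenic_downstream_1kbp")
  expect_equal(gap_class(1000L), "intergenic_downstream_1kbp")
  expect_equal(gap_class(1001L), "intergenic_downstream_5kbp")
  expect_equal(gap_class(5000L), "intergenic_downstream_5kbp")
  expect_equal(gap_class(5001L), "intergenic_downstream_10kbp")
  expect_equal(gap_class(10000L), "intergenic_downstream_10kbp")
  # 10,001 bp away: never associated
  lnc <- lnc_gene("L", p0 + 8000L + 10001L, p0 + 9000L + 10001L, "+")
  expect_true(is.na(find_partner(lnc, prots)))
})

test_that("classification is invariant under genome reflection with strand flip", {
  spec <- simulation_spec(seed = 23)
  ds <- simulate_annotations(spec)
  pairs <- classify_all(ds$genes, ds$genes)
  L <- max(vapply(ds$genes$genes, `[[`, integer(1), "end")) + 1000L
  flip <- function(g) {
    gene_annotation(g$gene_id, g$chrom, L - g$end, L - g$start,
                    if (g$strand == "+") "-" else "+",
                    exons = cbind(L - g$exons[, 2L], L - g$exons[, 1L]),
                    biotype = g$biotype)
  }
  mirrored <- gene_set(lapply(unname(ds$genes$genes), flip))
  pairs2 <- classify_all(mirrored, mirrored)
  expect_equal(sort(pairs2$ga_class), sort(pairs$ga_class))
  m <- match(pairs$lncrna_id, pairs2$lncrna_id)
  expect_equal(pairs2$ga_class[m], pairs$ga_class)
})

test_that("every associated pair receives exactly one of the 19 labels", {
  # fuzz: random lncRNA placed near a random protein; classification is total
  set.seed(99)
  tab <- ga_classes()$name
  for (i in 1:300) {
    p0 <- 50000L
    prot <- prot_gene("P", p0, strand = sample(c("+", "-"), 1))
    w <- sample(200:12000, 1)
    s <- p0 + sample(-22000:21000, 1)
    lnc <- lnc_gene("L", s, s + w, sample(c("+", "-"), 1))
    cl <- classify_pair(lnc, prot)
    gap <- max(0L, lnc$start - prot$end, prot$start - lnc$end)
    if (gap <= 10000L) {
      expect_false(is.null(cl))
      expect_true(cl$ga_class %in% tab)
    } else {
      expect_null(cl)
    }
  }
})

test_that("classify_all output is deterministic and reports unpaired lncRNAs", {
  ds <- simulate_annotations(simulation_spec(seed = 4))
  orphan <- lnc_gene("LNCZZZZ", 10 * 10^6, 10 * 10^6 + 500, chrom = "chrS")
  all_genes <- gene_set(c(unname(ds$genes$genes), list(orphan)))
  p1 <- classify_all(all_genes, all_genes)
  p2 <- classify_all(all_genes, all_genes)
  expect_identical(as.data.frame(p1), as.data.frame(p2))
  expect_equal(attr(p1, "unpaired"), "LNCZZZZ")
  expect_equal(length(attr(p1, "lnc_universe")), 20L)
  expect_equal(nrow(p1), 19L)
})
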