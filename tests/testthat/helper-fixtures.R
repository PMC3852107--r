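# Shared fixtures and independent oracles.

# Brute-force Kendall tau (tau-b): explicit all-pairs enumeration.
brute_kendall <- function(x, y) {
  n <- length(x)
  nc <- nd <- tx <- ty <- 0L
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    dx <- sign(x[j] - x[i]); dy <- sign(y[j] - y[i])
    if (dx == 0L && dy == 0L) { tx <- tx + 1L; ty <- ty + 1L }
    else if (dx == 0L) tx <- tx + 1L
    else if (dy == 0L) ty <- ty + 1L
    else if (dx == dy) nc <- nc + 1L
    else nd <- nd + 1L
  }
  n0 <- n * (n - 1L) / 2L
  den <- sqrt((n0 - tx) * (n0 - ty))
  if (den == 0) return(NA_real_)
  (nc - nd) / den
}

# Hypergeometric tail by direct summation of integer-binomial PMF terms.
brute_hyper_tail <- function(k, K, n, N, direction) {
  supp <- max(0L, n - (N - K)):min(K, n)
  pmf <- choose(K, supp) * choose(N - K, n - supp) / choose(N, n)
  if (direction == "over") sum(pmf[supp >= k]) else sum(pmf[supp <= k])
}

# A protein-coding gene with two exons and one intron, plus a lncRNA, used by
# the hand-built geometry cases. Coordinates are 0-based half-open.
prot_gene <- function(id = "P", start = 10000L, strand = "+",
                      chrom = "chr1") {
  gene_annotation(id, chrom, start, start + 8000L, strand,
                  exons = rbind(c(start, start + 2000L),
                                c(start + 6000L, start + 8000L)),
                  biotype = "protein_coding")
}

lnc_gene <- function(id = "L", start, end, strand = "+", chrom = "chr1") {
  gene_annotation(id, chrom, start, end, strand, biotype = "lncRNA")
}

# Expression set from per-gene replicate x timepoint matrices.
expr_fixture <- function(..., hours = c(0, 6, 24, 120)) {
  mats <- list(...)
  nr <- nrow(mats[[1L]])
  vals <- do.call(rbind, lapply(mats, as.vector))
  rownames(vals) <- names(mats)
  expression_set(vals,
                 replicates = rep(seq_len(nr), times = length(hours)),
                 hours = rep(hours, each = nr))
}

tc2 <- function(r1, r2) rbind(r1, r2)
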