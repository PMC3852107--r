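# Pairing of lncRNAs with their nearest protein-coding gene and assignment of
# one of the 19 genomic-architecture classes.

#' Classifier configuration
#'
#' @param radius association radius in bp (closest-edge distance).
#' @param bin_edges upper edges of the exclusive distance bins
#'   (0,e1], (e1,e2], (e2,e3].
#' @param promoter_window width in bp of the window immediately upstream of
#'   the protein TSS that defines promoter-associated lncRNAs.
#' @return list of class `ga_config`.
#' @export
ga_config <- function(radius = 10000L, bin_edges = c(1000L, 5000L, 10000L),
                      promoter_window = 1000L) {
  stopifnot(radius > 0, length(bin_edges) == 3L, all(diff(bin_edges) > 0),
            promoter_window > 0)
  structure(list(radius = as.integer(radius),
                 bin_edges = as.integer(bin_edges),
                 promoter_window = as.integer(promoter_window)),
            class = "ga_config")
}

distance_bin_label <- function(d, edges) {
  # d = 0 (abutting) falls in the first bin; d > edges[3] has no bin
  if (d > edges[3L]) return(NA_character_)
  c("1kbp", "5kbp", "10kbp")[findInterval(d, edges + 1L) + 1L]
}

# closest-edge distance between two spans (0 if overlapping/abutting)
edge_gap <- function(a_start, a_end, b_start, b_end) {
  max(0L, a_start - b_end, b_start - a_end)
}

#' Classify one lncRNA/protein-coding gene pair
#'
#' Assigns exactly one of the 19 GA classes by the first matching rule, in
#' priority order: intronic, exonic, embedding, head-to-head/tail-to-tail
#' (residual partial overlaps), promoter-associated, bidirectional promoter,
#' intergenic. See the package vignette for the full rule set.
#'
#' @param lnc,prot `gene_annotation` objects on the same chromosome; `prot`
#'   should be within the association radius of `lnc`.
#' @param config a [ga_config()].
#' @return list with `ga_class`, `superclass`, `distance_bin`, `orientation`,
#'   `edge_distance`, `tss_distance`, `overlap_bp`, or `NULL` when the pair is
#'   outside the association radius.
#' @export
classify_pair <- function(lnc, prot, config = ga_config()) {
  if (lnc$chrom != prot$chrom)
    stop("classify_pair: genes on different chromosomes (",
         lnc$chrom, " vs ", prot$chrom, ")")
  ov_s <- max(lnc$start, prot$start)
  ov_e <- min(lnc$end, prot$end)
  overlap_bp <- max(0L, ov_e - ov_s)
  edge_distance <- if (overlap_bp > 0L) 0L else
    edge_gap(lnc$start, lnc$end, prot$start, prot$end)
  tss_distance <- abs(tss(lnc) - tss(prot))
  same_strand <- lnc$strand == prot$strand
  sfx <- if (same_strand) "sense" else "antisense"

  name <- NA_character_
  if (overlap_bp > 0L) {
    name <- classify_overlap(lnc, prot, ov_s, ov_e, same_strand, sfx)
  } else {
    if (edge_distance > config$radius) return(NULL)
    name <- classify_disjoint(lnc, prot, same_strand, edge_distance,
                              tss_distance, config)
    if (is.na(name)) return(NULL)
  }
  tab <- ga_classes()
  row <- tab[tab$name == name, ]
  list(ga_class = name, superclass = row$superclass,
       distance_bin = row$distance_bin, orientation = row$orientation,
       edge_distance = edge_distance, tss_distance = tss_distance,
       overlap_bp = overlap_bp)
}

classify_overlap <- function(lnc, prot, ov_s, ov_e, same_strand, sfx) {
  intr <- introns(prot)
  # wholly inside one intron of the protein
  if (nrow(intr) > 0L &&
      any(lnc$start >= intr[, 1L] & lnc$end <= intr[, 2L]))
    return(paste0("intronic_", sfx))
  contained <- lnc$start >= prot$start && lnc$end <= prot$end
  contains <- prot$start >= lnc$start && prot$end <= lnc$end
  ex <- prot$exons
  exon_ov <- sum(pmax(0L, pmin(ov_e, ex[, 2L]) - pmax(ov_s, ex[, 1L])))
  intron_ov <- (ov_e - ov_s) - exon_ov
  if (contained && intron_ov == 0L) return(paste0("exonic_", sfx))
  if (contained || contains) return(paste0("embedding_", sfx))
  # residual partial overlap
  if (same_strand) {
    if (intron_ov == 0L) return("exonic_sense")
    return("embedding_sense")
  }
  in_ov <- function(x) x >= ov_s && x <= ov_e
  h2h <- in_ov(tss(lnc)) && in_ov(tss(prot))
  t2t <- in_ov(end3(lnc)) && in_ov(end3(prot))
  if (h2h && t2t) return("embedding_antisense")  # near-identical spans
  if (h2h) return("head_to_head")
  if (t2t) return("tail_to_tail")
  # degenerate: decide by which pair of ends is nearer
  if (abs(tss(lnc) - tss(prot)) <= abs(end3(lnc) - end3(prot)))
    "head_to_head" else "tail_to_tail"
}

classify_disjoint <- function(lnc, prot, same_strand, edge_distance,
                              tss_distance, config) {
  w <- config$promoter_window
  win <- if (prot$strand == "+") c(prot$start - w, prot$start) else
    c(prot$end, prot$end + w)
  # promoter-proximal: lncRNA contained entirely within the upstream window
  if (lnc$start >= win[1L] && lnc$end <= win[2L])
    return(paste0("promoter_associated_",
                  if (same_strand) "sense" else "antisense"))
  upstream <- if (prot$strand == "+") lnc$end <= prot$start else
    lnc$start >= prot$end
  divergent <- !same_strand && upstream
  if (divergent) {
    bin <- distance_bin_label(tss_distance, config$bin_edges)
    if (!is.na(bin)) return(paste0("bidirectional_promoter_", bin))
  }
  bin <- distance_bin_label(edge_distance, config$bin_edges)
  if (is.na(bin)) return(NA_character_)
  paste0(if (upstream) "intergenic_upstream_" else "intergenic_downstream_",
         bin)
}

#' Find the nearest protein-coding partner of a lncRNA
#'
#' Returns the protein-coding gene on the same chromosome minimising the
#' closest-edge distance (overlap counts as distance 0), or `NA` if no gene
#' lies within the association radius. Equal distances are broken by the
#' higher-priority GA class of the resulting pair, then lexicographically by
#' gene id.
#'
#' @param lnc a `gene_annotation` with biotype lncRNA.
#' @param proteins a [gene_set()] of protein-coding genes.
#' @param config a [ga_config()].
#' @return partner gene id, or `NA_character_`.
#' @export
find_partner <- function(lnc, proteins, config = ga_config()) {
  ids <- genes_on(proteins, lnc$chrom)
  if (!length(ids)) return(NA_character_)
  g <- proteins$genes[ids]
  gaps <- vapply(g, function(p)
    edge_gap(lnc$start, lnc$end, p$start, p$end), integer(1L))
  keep <- gaps <= config$radius
  if (!any(keep)) return(NA_character_)
  ids <- ids[keep]; gaps <- gaps[keep]
  best <- ids[gaps == min(gaps)]
  if (length(best) == 1L) return(best)
  tab <- ga_classes()
  prio <- vapply(best, function(id) {
    cl <- classify_pair(lnc, get_gene(proteins, id), config)
    if (is.null(cl)) nrow(tab) + 1L else match(cl$ga_class, tab$name)
  }, integer(1L))
  best <- best[prio == min(prio)]
  sort(best)[1L]
}

#' Classify all lncRNA/protein-coding gene pairs
#'
#' Pairs every lncRNA with its nearest protein-coding gene within the
#' association radius and assigns the GA class. Output order is deterministic
#' (chromosome, start, gene id). lncRNAs without a partner are reported in the
#' `"unpaired"` attribute; the full lncRNA universe (paired + unpaired) in the
#' `"lnc_universe"` attribute.
#'
#' @param lncs a [gene_set()] (only biotype-lncRNA members are used).
#' @param proteins a [gene_set()] (only protein-coding members are used).
#' @param config a [ga_config()].
#' @return data.frame of class `architecture_pairs` with one row per
#'   associated lncRNA: lncrna_id, partner_id, ga_class, superclass,
#'   distance_bin, orientation, edge_distance, tss_distance, overlap_bp, and
#'   the lncRNA coordinates (chrom, lnc_start, lnc_end, lnc_strand).
#' @export
classify_all <- function(lncs, proteins, config = ga_config()) {
  lncs <- filter_biotype(lncs, "lncRNA")
  proteins <- filter_biotype(proteins, "protein_coding")
  ids <- unlist(lncs$index, use.names = FALSE)  # sorted per chrom
  rows <- vector("list", length(ids))
  unpaired <- character(0)
  for (k in seq_along(ids)) {
    ln <- get_gene(lncs, ids[k])
    pid <- find_partner(ln, proteins, config)
    if (is.na(pid)) {
      unpaired <- c(unpaired, ids[k])
      next
    }
    cl <- classify_pair(ln, get_gene(proteins, pid), config)
    if (is.null(cl)) {
      unpaired <- c(unpaired, ids[k])
      next
    }
    rows[[k]] <- data.frame(
      lncrna_id = ids[k], partner_id = pid, ga_class = cl$ga_class,
      superclass = cl$superclass, distance_bin = cl$distance_bin,
      orientation = cl$orientation, edge_distance = cl$edge_distance,
      tss_distance = cl$tss_distance, overlap_bp = cl$overlap_bp,
      chrom = ln$chrom, lnc_start = ln$start, lnc_end = ln$end,
      lnc_strand = ln$strand, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1L))])
  if (is.null(out)) {
    out <- data.frame(lncrna_id = character(0), partner_id = character(0),
                      ga_class = character(0), superclass = character(0),
                      distance_bin = character(0), orientation = character(0),
                      edge_distance = integer(0), tss_distance = integer(0),
                      overlap_bp = integer(0), chrom = character(0),
                      lnc_start = integer(0), lnc_end = integer(0),
                      lnc_strand = character(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "unpaired") <- unpaired
  attr(out, "lnc_universe") <- ids
  class(out) <- c("architecture_pairs", class(out))
  out
}

#' Write a pair table as TSV
#' @param pairs result of [classify_all()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pairs_tsv <- function(pairs, path) {
  write.table(as.data.frame(pairs), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a pair table written by [write_pairs_tsv()]
#' @param path TSV path.
#' @return `architecture_pairs` data.frame.
#' @export
read_pairs_tsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  out <- read.delim(path, stringsAsFactors = FALSE)
  attr(out, "lnc_universe") <- out$lncrna_id
  attr(out, "unpaired") <- character(0)
  class(out) <- c("architecture_pairs", class(out))
  out
}
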