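# Readers/writers for the standard annotation formats. Parsing is delegated to
# rtracklayer; a light pre-validation pass supplies line-numbered errors for
# malformed records before the file is handed over.

gff3_data_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  which(!grepl("^\\s*(#|$)", lines))
}

#' Read gene annotations from a GFF3 file
#'
#' Gene features (1-based closed coordinates) are converted to the internal
#' 0-based half-open convention. Exon features are attached to their gene via
#' `Parent`, resolved through one level of transcript nesting if present;
#' overlapping exons from multiple transcripts are collapsed to their union.
#' Genes without exon children use the gene span as a single exon (with a
#' warning). Biotype is read from a configurable attribute; genes whose
#' biotype is neither lncRNA-like nor protein-coding are retained with
#' biotype "other".
#'
#' @param path GFF3 file path.
#' @param biotype_attr attribute keys tried in order for the gene biotype.
#' @return a [gene_set()].
#' @export
read_gff3 <- function(path, biotype_attr = c("gene_biotype", "gene_type")) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  data <- which(!grepl("^\\s*(#|$)", lines))
  nfield <- lengths(strsplit(lines[data], "\t", fixed = TRUE))
  if (any(nfield != 9L))
    stop("malformed GFF3 line ", data[which(nfield != 9L)[1L]],
         ": expected 9 tab-separated fields")
  gr <- rtracklayer::import(path, format = "gff3")
  mc <- as.data.frame(S4Vectors::mcols(gr))
  type <- as.character(mc$type)
  id <- if ("ID" %in% names(mc)) as.character(mc$ID) else rep(NA_character_, length(gr))
  parent <- if ("Parent" %in% names(mc)) {
    vapply(mc$Parent, function(p) if (length(p)) as.character(p)[1L] else NA_character_,
           character(1L))
  } else rep(NA_character_, length(gr))

  is_gene <- type == "gene"
  gene_idx <- which(is_gene)
  gene_ids <- id[gene_idx]
  if (anyNA(gene_ids)) stop("gene feature without ID attribute")
  if (anyDuplicated(gene_ids))
    stop("duplicate identifier: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))

  # map any feature id to its owning gene (self, or via one parent hop)
  owner <- setNames(gene_ids, gene_ids)
  mid <- which(!is_gene & !is.na(id) & !is.na(parent) & parent %in% gene_ids)
  owner2 <- setNames(owner[parent[mid]], id[mid])
  owner <- c(owner, owner2[!is.na(owner2)])

  biotype_of <- function(i) {
    for (key in biotype_attr) {
      if (key %in% names(mc)) {
        v <- as.character(mc[[key]][i])
        if (!is.na(v) && nzchar(v)) {
          if (v %in% c("lncRNA", "lincRNA", "lnc_RNA")) return("lncRNA")
          if (v == "protein_coding") return("protein_coding")
          return("other")
        }
      }
    }
    "other"
  }

  exon_idx <- which(type == "exon")
  exon_gene <- owner[parent[exon_idx]]
  st <- GenomicRanges::start(gr); en <- GenomicRanges::end(gr)
  exons_by_gene <- split(exon_idx, exon_gene)

  genes <- vector("list", length(gene_idx))
  for (j in seq_along(gene_idx)) {
    i <- gene_idx[j]
    gid <- gene_ids[j]
    ei <- exons_by_gene[[gid]]
    if (is.null(ei) || !length(ei)) {
      warning("gene ", gid, " has no exon children; using gene span")
      ex <- NULL
    } else {
      ir <- IRanges::reduce(IRanges::IRanges(st[ei] - 1L, width = en[ei] - st[ei] + 1L))
      ex <- cbind(IRanges::start(ir), IRanges::start(ir) + IRanges::width(ir))
    }
    genes[[j]] <- gene_annotation(
      gene_id = gid, chrom = as.character(GenomicRanges::seqnames(gr)[i]),
      start = st[i] - 1L, end = en[i],
      strand = as.character(GenomicRanges::strand(gr)[i]),
      exons = ex, biotype = biotype_of(i))
  }
  gene_set(genes)
}

#' Write a gene set as GFF3
#'
#' One `gene` feature per gene with `gene_biotype` attribute and one `exon`
#' child per exon. Deterministic ordering by (chromosome, start, gene_id).
#'
#' @param set a [gene_set()].
#' @param path output path.
#' @param source value for the GFF3 source column.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(set, path, source = "lncarch") {
  df <- as.data.frame(set)
  out <- c("##gff-version 3")
  for (k in seq_len(nrow(df))) {
    g <- get_gene(set, df$gene_id[k])
    bt <- switch(g$biotype, lncRNA = "lncRNA", protein_coding = "protein_coding", "other")
    out <- c(out, paste(g$chrom, source, "gene", g$start + 1L, g$end, ".",
                        g$strand, ".",
                        sprintf("ID=%s;gene_biotype=%s", g$gene_id, bt),
                        sep = "\t"))
    for (e in seq_len(nrow(g$exons))) {
      out <- c(out, paste(g$chrom, source, "exon",
                          g$exons[e, 1L] + 1L, g$exons[e, 2L], ".",
                          g$strand, ".",
                          sprintf("ID=%s.exon%d;Parent=%s", g$gene_id, e, g$gene_id),
                          sep = "\t"))
    }
  }
  writeLines(out, path)
  invisible(path)
}

#' Read gene annotations from a BED12 file
#'
#' BED's native 0-based half-open coordinates are kept as-is; blocks become
#' exons. All records are assigned the supplied biotype.
#'
#' @param path BED12 file path.
#' @param biotype biotype label for every record.
#' @return a [gene_set()].
#' @export
read_bed12 <- function(path, biotype = c("lncRNA", "protein_coding", "other")) {
  biotype <- match.arg(biotype)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  data <- which(!grepl("^\\s*(#|track|browser|$)", lines))
  for (ln in data) {
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1L]]
    if (length(f) != 12L)
      stop("malformed BED12 line ", ln, ": expected 12 tab-separated fields")
    if (!f[6L] %in% c("+", "-"))
      stop("strand required (line ", ln, ")")
    nb <- as.integer(f[10L])
    sizes <- strsplit(sub(",$", "", f[11L]), ",", fixed = TRUE)[[1L]]
    starts <- strsplit(sub(",$", "", f[12L]), ",", fixed = TRUE)[[1L]]
    if (length(sizes) != nb || length(starts) != nb)
      stop("blockSizes/blockStarts arity mismatch (line ", ln, ")")
  }
  gr <- rtracklayer::import(path, format = "bed")
  genes <- vector("list", length(gr))
  blocks <- gr$blocks
  for (i in seq_along(gr)) {
    start0 <- GenomicRanges::start(gr)[i] - 1L
    b <- blocks[[i]]  # 1-based, relative to chromStart
    ex <- cbind(start0 + IRanges::start(b) - 1L,
                start0 + IRanges::end(b))
    genes[[i]] <- gene_annotation(
      gene_id = as.character(gr$name[i]),
      chrom = as.character(GenomicRanges::seqnames(gr)[i]),
      start = start0, end = GenomicRanges::end(gr)[i],
      strand = as.character(GenomicRanges::strand(gr)[i]),
      exons = ex, biotype = biotype)
  }
  gene_set(genes)
}

#' Write a gene set as BED12
#'
#' @param set a [gene_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed12 <- function(set, path) {
  df <- as.data.frame(set)
  out <- character(0)
  for (k in seq_len(nrow(df))) {
    g <- get_gene(set, df$gene_id[k])
    ex <- g$exons
    out <- c(out, paste(g$chrom, g$start, g$end, g$gene_id, 0L, g$strand,
                        g$start, g$end, "0", nrow(ex),
                        paste0(paste(ex[, 2L] - ex[, 1L], collapse = ","), ","),
                        paste0(paste(ex[, 1L] - g$start, collapse = ","), ","),
                        sep = "\t"))
  }
  writeLines(out, path)
  invisible(path)
}

#' Write classified pairs as BED6+3
#'
#' One line per pair over the lncRNA span; extra columns carry the partner id,
#' GA class and super-class. Ordering is deterministic by coordinate.
#'
#' @param pairs a pair table from [classify_all()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pairs_bed <- function(pairs, path) {
  if (nrow(pairs) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  o <- order(pairs$chrom, pairs$lnc_start, pairs$lncrna_id)
  p <- pairs[o, , drop = FALSE]
  writeLines(paste(p$chrom, p$lnc_start, p$lnc_end, p$lncrna_id, 0L,
                   p$lnc_strand, p$partner_id, p$ga_class, p$superclass,
                   sep = "\t"), path)
  invisible(path)
}
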