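# Gene annotation domain types. All coordinates are 0-based half-open on the
# forward strand; conversions to/from 1-based formats happen only at I/O edges.

#' Create a single gene annotation
#'
#' @param gene_id unique gene identifier.
#' @param chrom chromosome name.
#' @param start,end 0-based half-open span (start < end).
#' @param strand "+" or "-".
#' @param exons two-column matrix of 0-based half-open (start, end) intervals,
#'   sorted, non-overlapping, each contained in the gene span. Defaults to the
#'   whole span as a single exon.
#' @param biotype one of "lncRNA", "protein_coding", "other".
#' @return An object of class `gene_annotation`.
#' @export
gene_annotation <- function(gene_id, chrom, start, end, strand,
                            exons = NULL,
                            biotype = c("lncRNA", "protein_coding", "other")) {
  biotype <- match.arg(biotype)
  start <- as.integer(start); end <- as.integer(end)
  if (!is.character(gene_id) || length(gene_id) != 1L || !nzchar(gene_id))
    stop("gene_id must be a non-empty string")
  if (is.na(start) || is.na(end) || start < 0L || start >= end)
    stop("invalid span for ", gene_id, ": require 0 <= start < end")
  if (!strand %in% c("+", "-"))
    stop("strand must be '+' or '-' for ", gene_id)
  if (is.null(exons)) exons <- cbind(start, end)
  exons <- matrix(as.integer(exons), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  if (nrow(exons) < 1L) stop("at least one exon required for ", gene_id)
  o <- order(exons[, 1L])
  exons <- exons[o, , drop = FALSE]
  if (any(exons[, 1L] >= exons[, 2L]))
    stop("exon with non-positive width in ", gene_id)
  if (any(exons[, 1L] < start) || any(exons[, 2L] > end))
    stop("exon outside gene span in ", gene_id)
  if (nrow(exons) > 1L && any(exons[-1L, 1L] < exons[-nrow(exons), 2L]))
    stop("overlapping exons in ", gene_id)
  structure(list(gene_id = gene_id, chrom = as.character(chrom),
                 start = start, end = end, strand = strand,
                 exons = exons, biotype = biotype),
            class = "gene_annotation")
}

#' Intron intervals of a gene
#'
#' @param gene a `gene_annotation`.
#' @return two-column matrix of 0-based half-open intron intervals (0 rows for
#'   single-exon genes).
#' @export
introns <- function(gene) {
  ex <- gene$exons
  if (nrow(ex) < 2L)
    return(matrix(integer(0), ncol = 2L,
                  dimnames = list(NULL, c("start", "end"))))
  cbind(start = ex[-nrow(ex), 2L], end = ex[-1L, 1L])
}

#' Transcription start site coordinate of a gene
#'
#' Returned in the 0-based half-open convention: the `start` boundary for "+"
#' genes and the `end` boundary for "-" genes.
#' @param gene a `gene_annotation`.
#' @return integer coordinate.
#' @export
tss <- function(gene) if (gene$strand == "+") gene$start else gene$end

# 3' boundary coordinate (the end opposite the TSS).
end3 <- function(gene) if (gene$strand == "+") gene$end else gene$start

#' Create a genome annotation set
#'
#' A keyed collection of [gene_annotation()] objects with a per-chromosome
#' index sorted by start coordinate.
#'
#' @param genes list of `gene_annotation` objects.
#' @return An object of class `gene_set`.
#' @export
gene_set <- function(genes = list()) {
  ids <- vapply(genes, `[[`, character(1L), "gene_id")
  if (anyDuplicated(ids))
    stop("duplicate identifier: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(genes) <- ids
  chroms <- vapply(genes, `[[`, character(1L), "chrom")
  starts <- vapply(genes, `[[`, integer(1L), "start")
  index <- lapply(split(seq_along(genes), chroms),
                  function(i) ids[i[order(starts[i], ids[i])]])
  structure(list(genes = genes, index = index), class = "gene_set")
}

#' @export
length.gene_set <- function(x) length(x$genes)

#' @export
print.gene_set <- function(x, ...) {
  bt <- table(vapply(x$genes, `[[`, character(1L), "biotype"))
  cat("gene_set with", length(x$genes), "genes on",
      length(x$index), "chromosome(s)\n")
  if (length(bt)) print(bt)
  invisible(x)
}

#' Retrieve one gene from a set
#' @param set a `gene_set`.
#' @param gene_id identifier.
#' @return a `gene_annotation`.
#' @export
get_gene <- function(set, gene_id) {
  g <- set$genes[[gene_id]]
  if (is.null(g)) stop("unknown gene_id: ", gene_id)
  g
}

#' Gene identifiers on one chromosome, sorted by start
#' @param set a `gene_set`.
#' @param chrom chromosome name.
#' @return character vector (possibly empty).
#' @export
genes_on <- function(set, chrom) {
  ids <- set$index[[chrom]]
  if (is.null(ids)) character(0) else ids
}

#' Subset a gene set by biotype
#' @param set a `gene_set`.
#' @param biotype biotype label to keep.
#' @return a `gene_set`.
#' @export
filter_biotype <- function(set, biotype) {
  keep <- vapply(set$genes, function(g) g$biotype == biotype, logical(1L))
  gene_set(unname(set$genes[keep]))
}

#' @export
as.data.frame.gene_set <- function(x, ...) {
  ids <- unlist(x$index, use.names = FALSE)
  g <- x$genes[ids]
  data.frame(gene_id = ids,
             chrom = vapply(g, `[[`, character(1L), "chrom"),
             start = vapply(g, `[[`, integer(1L), "start"),
             end = vapply(g, `[[`, integer(1L), "end"),
             strand = vapply(g, `[[`, character(1L), "strand"),
             biotype = vapply(g, `[[`, character(1L), "biotype"),
             n_exons = vapply(g, function(z) nrow(z$exons), integer(1L)),
             row.names = NULL, stringsAsFactors = FALSE)
}
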