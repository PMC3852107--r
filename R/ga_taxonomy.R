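# The 19-class genomic-architecture taxonomy and its 5 super-classes.

#' The genomic-architecture class table
#'
#' Nineteen classes describing the positional/orientational relationship of a
#' lncRNA gene with its nearest protein-coding gene, listed in rule-priority
#' order (first matching rule wins in [classify_pair()]). Orientation is
#' relative to the protein-coding gene; distance bins apply to bidirectional
#' (TSS-to-TSS distance) and intergenic (closest-edge distance) classes.
#'
#' @return data.frame with columns `name`, `superclass`, `distance_bin`,
#'   `orientation`, `priority`.
#' @export
ga_classes <- function() {
  df <- data.frame(
    name = c("intronic_sense", "intronic_antisense",
             "exonic_sense", "exonic_antisense",
             "embedding_sense", "embedding_antisense",
             "head_to_head", "tail_to_tail",
             "promoter_associated_sense", "promoter_associated_antisense",
             "bidirectional_promoter_1kbp", "bidirectional_promoter_5kbp",
             "bidirectional_promoter_10kbp",
             "intergenic_upstream_1kbp", "intergenic_upstream_5kbp",
             "intergenic_upstream_10kbp",
             "intergenic_downstream_1kbp", "intergenic_downstream_5kbp",
             "intergenic_downstream_10kbp"),
    superclass = c("intronic", "intronic",
                   "intronic", "antisense",
                   "intronic", "antisense",
                   "antisense", "antisense",
                   "promoter_associated", "promoter_associated",
                   rep("bidirectional", 3L),
                   rep("intergenic", 6L)),
    distance_bin = c(rep("none", 10L), rep(c("1kbp", "5kbp", "10kbp"), 3L)),
    orientation = c("sense", "antisense", "sense", "antisense",
                    "sense", "antisense", "antisense", "antisense",
                    "sense", "antisense", rep("antisense", 3L),
                    rep("n/a", 6L)),
    stringsAsFactors = FALSE)
  df$priority <- seq_len(nrow(df))
  df
}

#' Map a GA class to its super-class
#'
#' Total, deterministic mapping of the 19 class labels onto the five
#' super-classes (antisense, intronic, intergenic, bidirectional,
#' promoter_associated).
#'
#' @param ga character vector of GA class names.
#' @return character vector of super-class labels.
#' @export
superclass_of <- function(ga) {
  tab <- ga_classes()
  m <- match(ga, tab$name)
  if (anyNA(m)) stop("unknown GA class: ", paste(ga[is.na(m)], collapse = ", "))
  tab$superclass[m]
}

#' The five super-class labels
#' @return character vector of length 5.
#' @export
ga_superclasses <- function() {
  c("antisense", "intronic", "intergenic", "bidirectional", "promoter_associated")
}
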