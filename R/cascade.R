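# The five-step filtration cascade: all lncRNAs on the array -> differentially
# expressed -> protein-associated -> partner differentially expressed ->
# sign-correlated with the partner. Memberships are nested by construction.

cascade_step_names <- function() {
  c("on_array", "differentially_expressed", "protein_associated",
    "partner_differentially_expressed", "correlated")
}

#' Run the filtration cascade
#'
#' @param pairs an `architecture_pairs` table from [classify_all()] (its
#'   `lnc_universe` attribute, when present, defines the full lncRNA set
#'   including unpaired genes).
#' @param se expression `SummarizedExperiment` holding both lncRNA and
#'   partner genes. lncRNAs without an expression row are dropped with a
#'   warning; pairs whose partner lacks a row fail the partner-DE step.
#' @param cfg an [analysis_config()].
#' @param mode_family optionally "rate" or "magnitude" to add per-step dynamic
#'   mode frequency tables.
#' @return object of class `cascade_result`: list with `membership` (one row
#'   per lncRNA with per-step flags, correlation sign and GA labels), `steps`
#'   (named list of member id vectors), `tables` (per step, frequency tables
#'   of super-classes, GA classes and, when requested, modes), `config`,
#'   `n_dropped`.
#' @export
run_filtration_cascade <- function(pairs, se, cfg = analysis_config(),
                                   mode_family = NULL) {
  universe <- attr(pairs, "lnc_universe")
  if (is.null(universe)) universe <- unique(pairs$lncrna_id)
  universe <- sort(universe)
  on_array <- universe %in% rownames(se)
  n_dropped <- sum(!on_array)
  if (n_dropped > 0L)
    warning(n_dropped, " lncRNA(s) without expression rows dropped")
  ids <- universe[on_array]

  pmap <- setNames(pairs$partner_id, pairs$lncrna_id)
  gmap <- setNames(pairs$ga_class, pairs$lncrna_id)
  smap <- setNames(pairs$superclass, pairs$lncrna_id)

  de_of <- local({
    cache <- new.env(parent = emptyenv())
    function(g) {
      if (!g %in% rownames(se)) return(NA)
      if (is.null(cache[[g]]))
        cache[[g]] <- is_differentially_expressed(timecourse(se, g), cfg)$de
      cache[[g]]
    }
  })

  de <- vapply(ids, de_of, logical(1L))
  assoc <- de & ids %in% names(pmap)
  partner_de <- assoc
  partner_de[assoc] <- vapply(ids[assoc], function(g) {
    isTRUE(de_of(pmap[[g]]))
  }, logical(1L))
  sign <- rep("none", length(ids))
  tau <- rep(NA_real_, length(ids))
  for (k in which(partner_de)) {
    cp <- correlate_pair(timecourse(se, ids[k]),
                         timecourse(se, pmap[[ids[k]]]), cfg)
    sign[k] <- cp$sign; tau[k] <- cp$tau
  }
  correlated <- partner_de & sign != "none"

  membership <- data.frame(
    gene_id = ids, on_array = TRUE, differentially_expressed = de,
    protein_associated = assoc, partner_differentially_expressed = partner_de,
    correlated = correlated, correlation_sign = sign, tau = tau,
    partner_id = unname(pmap[ids]), ga_class = unname(gmap[ids]),
    superclass = unname(smap[ids]),
    row.names = NULL, stringsAsFactors = FALSE)

  if (!is.null(mode_family)) {
    ma <- assign_modes(se[rownames(se) %in% ids, , drop = FALSE], mode_family,
                       cfg$profile_stat)
    membership$mode <- ma$mode[match(ids, ma$gene_id)]
  }

  steps <- list(
    on_array = ids,
    differentially_expressed = ids[de],
    protein_associated = ids[assoc],
    partner_differentially_expressed = ids[partner_de],
    correlated = ids[correlated])

  all_classes <- ga_classes()$name
  all_super <- ga_superclasses()
  tabulate_step <- function(members) {
    m <- membership[membership$gene_id %in% members & !is.na(membership$ga_class), ]
    out <- list(
      superclass = table(factor(m$superclass, levels = all_super)),
      ga_class = table(factor(m$ga_class, levels = all_classes)))
    if (!is.null(mode_family)) {
      lev <- enumerate_modes(mode_family)$name
      out$mode <- table(factor(membership$mode[membership$gene_id %in% members],
                               levels = lev))
    }
    out
  }
  tables <- lapply(steps, tabulate_step)

  structure(list(membership = membership, steps = steps, tables = tables,
                 config = cfg, mode_family = mode_family,
                 n_dropped = n_dropped),
            class = "cascade_result")
}

#' @export
print.cascade_result <- function(x, ...) {
  cat("filtration cascade:\n")
  for (s in names(x$steps))
    cat(sprintf("  %-34s %d\n", s, length(x$steps[[s]])))
  invisible(x)
}

#' Write cascade membership and per-step tables as TSV
#' @param cascade a `cascade_result`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cascade_tsv <- function(cascade, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(cascade$membership, file.path(dir, "cascade_membership.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  rows <- list()
  for (s in names(cascade$tables)) {
    for (what in names(cascade$tables[[s]])) {
      tb <- cascade$tables[[s]][[what]]
      rows[[length(rows) + 1L]] <- data.frame(
        step = s, labelling = what, label = names(tb),
        count = as.integer(tb), stringsAsFactors = FALSE)
    }
  }
  write.table(do.call(rbind, rows), file.path(dir, "cascade_tables.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
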