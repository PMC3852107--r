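# Pipeline orchestration: simulate / classify / analyze as plain R functions
# writing stable TSV outputs plus a run manifest. A thin command-line wrapper
# lives in exec/lncarch.

#' Read a pipeline configuration from YAML
#'
#' Recognised keys mirror the arguments of [analysis_config()],
#' [ga_config()] and [simulation_spec()]; unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return named list of configuration values.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  cfg <- yaml::read_yaml(path)
  known <- c("seed", "radius", "bin_edges", "promoter_window",
             "tau_threshold", "fc_threshold", "subset_size", "corr_threshold",
             "profile_stat", "mode_family", "noise_sigma", "n_replicates",
             "timepoints", "baseline", "dynamic_range", "n_pairs_per_class",
             "spacing", "chrom", "chrom_length")
  bad <- setdiff(names(cfg), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  cfg
}

config_take <- function(cfg, fn) {
  args <- cfg[intersect(names(cfg), names(formals(fn)))]
  do.call(fn, args)
}

#' Simulate a dataset and write it to disk
#'
#' Writes `genes.gff3`, `genes.bed12`, `expression.tsv` and `truth.tsv` into
#' `out_dir`.
#'
#' @param spec a [simulation_spec()], or a YAML path of configuration values.
#' @param out_dir output directory (created if missing).
#' @param seed optional seed overriding the spec's.
#' @return the simulated dataset (list genes/se/truth), invisibly.
#' @export
run_simulate <- function(spec = simulation_spec(), out_dir, seed = NULL) {
  if (is.character(spec)) spec <- config_take(read_pipeline_config(spec),
                                              simulation_spec)
  if (!is.null(seed)) spec$seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ds <- simulate_dataset(spec)
  write_gff3(ds$genes, file.path(out_dir, "genes.gff3"))
  write_bed12(ds$genes, file.path(out_dir, "genes.bed12"))
  if (!is.null(ds$se))
    write_expression_tsv(ds$se, file.path(out_dir, "expression.tsv"))
  write.table(ds$truth, file.path(out_dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(ds)
}

#' Classify annotations and write the pair table
#'
#' Writes `pairs.tsv` and `pairs.bed` into `out_dir`.
#'
#' @param annotations a [gene_set()] or a GFF3 path holding both lncRNA and
#'   protein-coding genes.
#' @param out_dir output directory.
#' @param config a [ga_config()].
#' @return the pair table, invisibly.
#' @export
run_classify <- function(annotations, out_dir, config = ga_config()) {
  if (is.character(annotations)) {
    if (!file.exists(annotations)) stop("no such file: ", annotations)
    annotations <- read_gff3(annotations)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pairs <- classify_all(annotations, annotations, config)
  write_pairs_tsv(pairs, file.path(out_dir, "pairs.tsv"))
  write_pairs_bed(pairs, file.path(out_dir, "pairs.bed"))
  invisible(pairs)
}

#' Run the expression analysis stage
#'
#' Differential-expression calls, dynamic-mode assignments, pair
#' correlations, the filtration cascade and super-class enrichment across
#' consecutive steps, all written as TSV plus a `manifest.yaml` enabling
#' reproducible reruns.
#'
#' @param pairs an `architecture_pairs` table or a `pairs.tsv` path.
#' @param expression an expression `SummarizedExperiment` or TSV path.
#' @param out_dir output directory.
#' @param cfg an [analysis_config()].
#' @param mode_family "rate" or "magnitude".
#' @return list with cascade, de, modes, enrichment, invisibly.
#' @export
run_analyze <- function(pairs, expression, out_dir,
                        cfg = analysis_config(), mode_family = "rate") {
  if (is.character(pairs)) pairs <- read_pairs_tsv(pairs)
  if (is.character(expression)) expression <- read_expression_tsv(expression)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  de <- de_calls(expression, cfg)
  write.table(de, file.path(out_dir, "de_calls.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  modes <- assign_modes(expression, mode_family, cfg$profile_stat)
  write.table(modes, file.path(out_dir, "modes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  n_warn <- 0L
  cascade <- withCallingHandlers(
    run_filtration_cascade(pairs, expression, cfg, mode_family = mode_family),
    warning = function(w) {
      n_warn <<- n_warn + 1L
      invokeRestart("muffleWarning")
    })
  write_cascade_tsv(cascade, out_dir)

  enrich <- list()
  for (s in names(cascade$steps)[-1L]) {
    res <- tryCatch(class_shift_tests(cascade, s, "superclass", "class_vs_rest"),
                    error = function(e) NULL)
    if (!is.null(res)) enrich[[s]] <- res
  }
  enrichment <- if (length(enrich)) do.call(rbind, enrich) else NULL
  if (!is.null(enrichment))
    write_enrichment_tsv(enrichment, file.path(out_dir, "enrichment.tsv"))

  manifest <- list(
    package = "lncarch",
    version = as.character(packageVersion("lncarch")),
    analysis_config = unclass(cfg),
    mode_family = mode_family,
    n_genes = nrow(expression),
    n_pairs = nrow(pairs),
    n_warnings = n_warn,
    step_sizes = lapply(cascade$steps, length))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(list(cascade = cascade, de = de, modes = modes,
                 enrichment = enrichment))
}
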