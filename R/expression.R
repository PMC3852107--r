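# Expression-matrix I/O and the differential-expression machinery: Kendall-tau
# replicate concordance on timepoint subsets plus an endpoint fold-change rule.
# Intensities are raw (linear-scale) array values; no normalization is applied.

#' Analysis configuration
#'
#' Thresholds for the differential-expression and pair-correlation rules.
#' On three untied points Kendall's tau takes values in {-1, -1/3, 1/3, 1},
#' so the default `tau_threshold` of 0.6 admits only perfect rank agreement
#' on a timepoint subset; on four untied points the admissible |tau| values
#' at the default `corr_threshold` are exactly {2/3, 1}.
#'
#' @param tau_threshold replicate-concordance cutoff (strict: tau must exceed it).
#' @param fc_threshold endpoint fold-change cutoff (non-strict: FC >= cutoff).
#' @param subset_size length of the timepoint subsets on which concordance is
#'   evaluated ("any three of the four").
#' @param corr_threshold lncRNA-protein correlation cutoff (non-strict).
#' @param profile_stat statistic collapsing replicates to one profile for
#'   correlation and mode assignment.
#' @return list of class `analysis_config`.
#' @export
analysis_config <- function(tau_threshold = 0.6, fc_threshold = 1.5,
                            subset_size = 3L, corr_threshold = 0.6,
                            profile_stat = c("mean", "median")) {
  profile_stat <- match.arg(profile_stat)
  stopifnot(tau_threshold > 0, fc_threshold > 0, corr_threshold > 0,
            subset_size >= 2L)
  structure(list(tau_threshold = tau_threshold, fc_threshold = fc_threshold,
                 subset_size = as.integer(subset_size),
                 corr_threshold = corr_threshold,
                 profile_stat = profile_stat),
            class = "analysis_config")
}

#' Build an expression set from a replicate x timepoint array
#'
#' @param values numeric matrix, rows = genes (rownames = gene ids), columns =
#'   replicate x timepoint combinations.
#' @param replicates integer vector, replicate index per column.
#' @param hours numeric vector, timepoint (hours) per column.
#' @return a [SummarizedExperiment::SummarizedExperiment] with assay
#'   `intensity` and colData columns `replicate` and `hours`; columns are
#'   ordered canonically (by replicate, then hours).
#' @export
expression_set <- function(values, replicates, hours) {
  stopifnot(is.matrix(values), ncol(values) == length(replicates),
            length(replicates) == length(hours), !is.null(rownames(values)))
  if (anyNA(values)) stop("missing values in expression matrix")
  if (any(values < 0)) stop("negative intensities in expression matrix")
  if (length(unique(replicates)) < 2L) stop("at least 2 replicates required")
  o <- order(replicates, hours)
  values <- values[, o, drop = FALSE]
  replicates <- as.integer(replicates[o]); hours <- hours[o]
  colnames(values) <- sprintf("r%d_t%g", replicates, hours)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(intensity = values),
    colData = S4Vectors::DataFrame(replicate = replicates, hours = hours))
}

#' Read a replicated expression timecourse TSV
#'
#' Header columns (other than the first, the gene id) must follow the pattern
#' `r<replicate>_t<hours>`, e.g. `r1_t0`, `r2_t120`. Column order in the file
#' is irrelevant; parsing is header-driven.
#'
#' @param path TSV path.
#' @return a `SummarizedExperiment` as in [expression_set()].
#' @export
read_expression_tsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("expected gene id plus replicate x timepoint columns")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate identifier: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  cols <- colnames(df)[-1L]
  m <- regmatches(cols, regexec("^r([0-9]+)_t([0-9]+(\\.[0-9]+)?)$", cols))
  bad <- lengths(m) == 0L | vapply(m, length, integer(1L)) < 3L
  if (any(bad))
    stop("unrecognised expression column header: ",
         paste(cols[bad], collapse = ", "),
         " (expected r<replicate>_t<hours>)")
  reps <- vapply(m, function(x) as.integer(x[2L]), integer(1L))
  hours <- vapply(m, function(x) as.numeric(x[3L]), numeric(1L))
  vals <- as.matrix(df[, -1L, drop = FALSE])
  if (anyNA(vals)) {
    idx <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    stop("missing value for gene ", ids[idx[1L]], " in column ",
         cols[idx[2L]])
  }
  if (any(vals < 0)) {
    idx <- which(vals < 0, arr.ind = TRUE)[1L, ]
    stop("negative intensity for gene ", ids[idx[1L]], " in column ",
         cols[idx[2L]])
  }
  rownames(vals) <- ids
  expression_set(vals, reps, hours)
}

#' Write an expression set as TSV
#' @param se expression `SummarizedExperiment`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(se, path) {
  vals <- SummarizedExperiment::assay(se, "intensity")
  df <- data.frame(gene_id = rownames(vals), vals, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Timepoints of an expression set
#' @param se expression `SummarizedExperiment`.
#' @return sorted unique hours.
#' @export
timepoints <- function(se) sort(unique(SummarizedExperiment::colData(se)$hours))

#' Extract one gene's replicate x timepoint matrix
#' @param se expression `SummarizedExperiment`.
#' @param gene_id gene identifier.
#' @return numeric matrix, rows = replicates, columns = timepoints (sorted).
#' @export
timecourse <- function(se, gene_id) {
  if (!gene_id %in% rownames(se)) stop("no expression row for gene ", gene_id)
  cd <- SummarizedExperiment::colData(se)
  v <- SummarizedExperiment::assay(se, "intensity")[gene_id, ]
  reps <- sort(unique(cd$replicate)); hrs <- sort(unique(cd$hours))
  out <- matrix(NA_real_, length(reps), length(hrs),
                dimnames = list(paste0("r", reps), paste0("t", hrs)))
  for (i in seq_along(reps)) for (j in seq_along(hrs)) {
    k <- which(cd$replicate == reps[i] & cd$hours == hrs[j])
    if (length(k) != 1L)
      stop("gene ", gene_id, ": expected exactly one cell for replicate ",
           reps[i], " at ", hrs[j], " h")
    out[i, j] <- v[k]
  }
  out
}

#' Collapse a timecourse to a single profile across replicates
#' @param tc replicate x timepoint matrix.
#' @param stat "mean" or "median".
#' @return numeric vector over timepoints.
#' @export
profile_of <- function(tc, stat = c("mean", "median")) {
  stat <- match.arg(stat)
  if (stat == "mean") colMeans(tc) else apply(tc, 2L, median)
}

#' Kendall's rank correlation
#'
#' tau = (concordant - discordant) / number of pairs, with tau-b style
#' denominator correction in the presence of ties. Returns `NA` when either
#' vector is constant (tau undefined).
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return tau in \[-1, 1\] (or `NA`).
#' @export
kendall_tau <- function(x, y) {
  if (length(x) != length(y)) stop("kendall_tau: unequal lengths")
  if (length(x) < 2L) stop("kendall_tau: need length >= 2")
  suppressWarnings(cor(x, y, method = "kendall"))
}

#' Endpoint fold change of a timecourse
#'
#' Direction-symmetric ratio (>= 1) of the replicate-mean intensities at the
#' first and last timepoints.
#'
#' @param tc replicate x timepoint matrix.
#' @return fold change >= 1.
#' @export
fold_change <- function(tc) {
  m1 <- mean(tc[, 1L]); m2 <- mean(tc[, ncol(tc)])
  if (min(m1, m2) <= 0) stop("fold_change: zero endpoint intensity")
  max(m1, m2) / min(m1, m2)
}

#' Differential-expression call for one timecourse
#'
#' A gene is differentially expressed when (i) there exists a timepoint subset
#' of size `subset_size` on which every pair of replicate profiles has
#' Kendall's tau strictly above `tau_threshold`, and (ii) the endpoint fold
#' change is at least `fc_threshold`.
#'
#' @param tc replicate x timepoint matrix (>= 2 replicates).
#' @param cfg an [analysis_config()].
#' @return list with `de` (logical), `concordant` (logical), `fold_change`,
#'   and `qualifying_subsets` (list of timepoint index vectors).
#' @export
is_differentially_expressed <- function(tc, cfg = analysis_config()) {
  nt <- ncol(tc); nr <- nrow(tc)
  if (nr < 2L) stop("at least 2 replicates required")
  if (cfg$subset_size > nt) stop("subset_size exceeds number of timepoints")
  subs <- combn(nt, cfg$subset_size, simplify = FALSE)
  rep_pairs <- combn(nr, 2L, simplify = FALSE)
  ok <- vapply(subs, function(s) {
    all(vapply(rep_pairs, function(rp) {
      tau <- kendall_tau(tc[rp[1L], s], tc[rp[2L], s])
      !is.na(tau) && tau > cfg$tau_threshold
    }, logical(1L)))
  }, logical(1L))
  fc <- fold_change(tc)
  list(de = any(ok) && fc >= cfg$fc_threshold,
       concordant = any(ok),
       fold_change = fc,
       qualifying_subsets = subs[ok])
}

#' Differential-expression calls for every gene in an expression set
#' @param se expression `SummarizedExperiment`.
#' @param cfg an [analysis_config()].
#' @return data.frame with gene_id, de, concordant, fold_change.
#' @export
de_calls <- function(se, cfg = analysis_config()) {
  ids <- rownames(se)
  res <- lapply(ids, function(g) is_differentially_expressed(timecourse(se, g), cfg))
  data.frame(gene_id = ids,
             de = vapply(res, `[[`, logical(1L), "de"),
             concordant = vapply(res, `[[`, logical(1L), "concordant"),
             fold_change = vapply(res, `[[`, numeric(1L), "fold_change"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Correlation sign of a lncRNA-protein pair
#'
#' Kendall's tau between the two collapsed (replicate-mean by default)
#' timepoint profiles; "+" when tau >= `corr_threshold`, "-" when
#' tau <= -`corr_threshold`, otherwise "none".
#'
#' @param lnc_tc,prot_tc replicate x timepoint matrices on the same timepoints.
#' @param cfg an [analysis_config()].
#' @return list with `sign` in {"+", "-", "none"} and `tau`.
#' @export
correlate_pair <- function(lnc_tc, prot_tc, cfg = analysis_config()) {
  if (ncol(lnc_tc) != ncol(prot_tc))
    stop("correlate_pair: timepoint mismatch")
  p1 <- profile_of(lnc_tc, cfg$profile_stat)
  p2 <- profile_of(prot_tc, cfg$profile_stat)
  tau <- kendall_tau(p1, p2)
  sign <- if (is.na(tau)) "none"
  else if (tau >= cfg$corr_threshold) "+"
  else if (tau <= -cfg$corr_threshold) "-"
  else "none"
  list(sign = sign, tau = tau)
}
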